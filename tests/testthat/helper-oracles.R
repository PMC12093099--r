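# Independent oracles used to validate production code. These deliberately
# re-derive each quantity by brute force or closed form, without calling the
# package functions they check.

# O(residues x nucleotides x snapshots) double-loop HPR extraction.
brute_force_hpr <- function(snapshots, d_min = 3, d_max = 7) {
  snaps <- if (inherits(snapshots[[1]], "cas9_snapshot")) snapshots else
    unlist(snapshots, recursive = FALSE)
  hits <- c()
  for (s in snaps) {
    for (i in seq_len(nrow(s$residues))) {
      for (j in seq_len(nrow(s$nucleotides))) {
        d <- sqrt((s$residues$x[i] - s$nucleotides$x[j])^2 +
                    (s$residues$y[i] - s$nucleotides$y[j])^2 +
                    (s$residues$z[i] - s$nucleotides$z[j])^2)
        if (d >= d_min && d <= d_max) hits <- c(hits, s$residues$resno[i])
      }
    }
  }
  sort(unique(hits))
}

# Average ranks (midranks) computed by sorting, not via rank().
midranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Product-moment correlation from the textbook formula.
pearson_formula <- function(a, b) {
  am <- a - sum(a) / length(a)
  bm <- b - sum(b) / length(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

spearman_formula <- function(a, b) pearson_formula(midranks(a), midranks(b))

# Exact interventional Shapley values by subset enumeration against a
# background matrix: v(S) = mean_b f(x_S, b_{~S}).
brute_force_shapley <- function(predict_fn, x, background) {
  p <- length(x)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  v <- apply(subsets, 1, function(S) {
    hyb <- background
    hyb[, S] <- matrix(x[S], nrow(background), sum(S), byrow = TRUE)
    mean(predict_fn(hyb))
  })
  key <- apply(subsets, 1, function(S) paste(which(S), collapse = ","))
  vof <- function(S) v[match(paste(sort(S), collapse = ","), key)]
  phi <- numeric(p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    for (k in 0:length(others)) {
      combs <- if (k == 0) list(integer(0)) else
        utils::combn(others, k, simplify = FALSE)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      for (S in combs) phi[j] <- phi[j] + w * (vof(c(S, j)) - vof(S))
    }
  }
  phi
}

# Gaussian KL divergence by numerical integration of the defining integral.
numeric_kl <- function(mu1, sd1, mu0, sd0) {
  stats::integrate(function(x)
    stats::dnorm(x, mu1, sd1) * (stats::dnorm(x, mu1, sd1, log = TRUE) -
                                   stats::dnorm(x, mu0, sd0, log = TRUE)),
    lower = mu1 - 12 * sd1, upper = mu1 + 12 * sd1,
    rel.tol = 1e-10)$value
}

# Random rigid motion (rotation + translation) applied to a coordinate
# data.frame with x/y/z columns.
apply_rigid <- function(df, R, t) {
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
  df$x <- xyz[, 1] + t[1]; df$y <- xyz[, 2] + t[2]; df$z <- xyz[, 3] + t[3]
  df
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

rigid_snapshot <- function(snapshot, R, t) {
  snapshot$residues <- apply_rigid(snapshot$residues, R, t)
  snapshot$nucleotides <- apply_rigid(snapshot$nucleotides, R, t)
  snapshot
}
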