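# Small study configurations shared across tests.

tiny_config <- function(...) {
  args <- list(...)
  base <- list(n_trajectories = 6L, n_snapshots_per_trajectory = 8L,
               n_residues = 20L, n_proximal_residues = 10L,
               n_descriptors = 8L, n_informative_features = 4L,
               noise_sd = 0.1, label_noise_sd = 0, jitter_sd = 0.2,
               seed = 42L)
  base[names(args)] <- args
  do.call(synthetic_config, base)
}

std_dataset <- function(n = 32, p = 3, seed = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- 0.4 + 0.3 * X[, 1] - 0.2 * X[, min(2, p)] + rnorm(n, 0, 0.05)
  list(X = X, y = y)
}

tiny_dataset <- function(config = tiny_config(), ...) {
  sim <- synthetic_dataset(config, ...)
  hpr <- compute_hpr_set(sim$snapshots)
  list(sim = sim,
       dataset = assemble_matrix(sim$table, hpr, sim$activities),
       hpr = hpr)
}
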