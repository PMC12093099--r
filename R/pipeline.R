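# The three-step prediction pipeline: standardisation, surrogate-importance
# feature selection, final regressor; plus splits, grid search, the
# model-pair averaging rule, the Spearman-change feature-size rule and
# evaluation.

spearman_cor <- function(a, b) stats::cor(a, b, method = "spearman")

fit_scaler <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1  # zero-variance features: centered, scale left at 1
  list(center = center, scale = scale)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' Train/test split with five-fold cross-validation plan
#'
#' The test partition holds the last `n_holdout` snapshots (by snapshot
#' number) of every trajectory; the remaining rows are partitioned at random
#' (seeded) into `n_folds` near-equal cross-validation folds.
#'
#' @param dataset A `nanoenv_dataset`.
#' @param n_holdout Snapshots held out per trajectory (default 4).
#' @param cv_seed Seed for the fold assignment.
#' @param n_folds Number of folds (default 5).
#' @return A `split_plan`: `train_rows`, `test_rows` (row indices), `folds`
#'   (list of validation index vectors partitioning `train_rows`).
#' @export
make_split <- function(dataset, n_holdout = 4L, cv_seed = 1L, n_folds = 5L) {
  info <- dataset$row_info
  snap_no <- vapply(info$snapshot_id,
                    function(s) parse_snapshot_id(s)$snapshot_number, 0L)
  test <- integer(0)
  for (tr in unique(info$trajectory)) {
    rows <- which(info$trajectory == tr)
    if (length(rows) <= n_holdout)
      stop("trajectory ", tr, " has only ", length(rows),
           " snapshots (need > n_holdout = ", n_holdout, ")")
    test <- c(test, rows[order(snap_no[rows])][
      seq(length(rows) - n_holdout + 1L, length(rows))])
  }
  test <- sort(test)
  train <- setdiff(seq_len(nrow(info)), test)
  set.seed(cv_seed)
  shuffled <- sample(train)
  # near-equal sizes: assign cyclically over the shuffled order
  fold_id <- rep(seq_len(n_folds), length.out = length(shuffled))
  folds <- lapply(seq_len(n_folds), function(k) sort(shuffled[fold_id == k]))
  structure(list(train_rows = train, test_rows = test, folds = folds,
                 n_holdout = n_holdout, cv_seed = cv_seed),
            class = "split_plan")
}

#' Fit the three-step pipeline
#'
#' Standardizes the training columns (zero mean, unit variance; constant
#' columns are centered only), fits surrogate `m1` on all features, keeps
#' the `f` features with the highest `m1` importance (ties broken by
#' ascending column index), and fits `m2` on the selected standardized
#' columns.
#'
#' @param X Numeric training matrix (raw scale).
#' @param y Activity labels.
#' @param m1,m2 Family names (see [surrogate_families()],
#'   [final_families()]).
#' @param f Number of features to select.
#' @param seed Seed passed to both model fits.
#' @return A `fitted_pipeline`: `scaler`, `m1_model`, `selected` (column
#'   names), `selected_idx`, `m2_model`, `spec`.
#' @export
fit_pipeline <- function(X, y, m1, m2, f, seed = 1L) {
  if (!nrow(X)) stop("empty training data")
  if (f > ncol(X))
    stop("f = ", f, " exceeds the number of available features (", ncol(X), ")")
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(X, scaler)
  m1_model <- fit_family(m1, Xs, y, seed = seed)
  imp <- feature_importance(m1_model)
  ord <- order(-imp, seq_along(imp))
  sel <- ord[seq_len(f)]
  m2_model <- fit_family(m2, Xs[, sel, drop = FALSE], y, seed = seed)
  structure(list(scaler = scaler, m1_model = m1_model,
                 selected = colnames(X)[sel], selected_idx = sel,
                 m2_model = m2_model,
                 spec = list(m1 = m1, m2 = m2, f = f, seed = seed)),
            class = "fitted_pipeline")
}

#' @export
predict.fitted_pipeline <- function(object, newdata, ...) {
  Xs <- apply_scaler(newdata, object$scaler)
  predict(object$m2_model, Xs[, object$selected_idx, drop = FALSE])
}

#' Enumerate the pipeline hyperparameter grid
#'
#' @param m1_families,m2_families Family name vectors.
#' @param feature_sizes Candidate feature-set sizes F (default 5,10,...,50).
#' @return data.frame with one row per (m1, m2, f) cell in declaration
#'   order; the default grid has 5 x 6 x 10 = 300 rows.
#' @export
default_grid <- function(m1_families = surrogate_families(),
                         m2_families = final_families(),
                         feature_sizes = seq(5L, 50L, by = 5L)) {
  expand.grid(m1 = m1_families, m2 = m2_families, f = feature_sizes,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Grid search with k-fold cross-validation
#'
#' Evaluates every (m1, m2, f) grid cell by the mean over folds of the
#' validation Spearman correlation between predicted and true activity.
#' The surrogate is fitted once per (fold, m1) and its feature ranking
#' reused across f and m2. Cells that fail to fit are recorded as missing
#' with a warning and the run continues.
#'
#' @param dataset A `nanoenv_dataset`.
#' @param split A `split_plan` from [make_split()].
#' @param m1_families,m2_families,feature_sizes Grid axes.
#' @param seed Seed passed to every model fit.
#' @return A `cv_result`: `cells` (data.frame m1, m2, f, fold, spearman) and
#'   `grid` metadata.
#' @export
grid_search <- function(dataset, split,
                        m1_families = surrogate_families(),
                        m2_families = final_families(),
                        feature_sizes = seq(5L, 50L, by = 5L),
                        seed = 1L) {
  X <- dataset$X
  y <- dataset$activity
  cells <- list()
  for (k in seq_along(split$folds)) {
    val <- split$folds[[k]]
    tr <- setdiff(split$train_rows, val)
    scaler <- fit_scaler(X[tr, , drop = FALSE])
    Xtr <- apply_scaler(X[tr, , drop = FALSE], scaler)
    Xva <- apply_scaler(X[val, , drop = FALSE], scaler)
    for (m1 in m1_families) {
      ord <- tryCatch({
        m1_fit <- fit_family(m1, Xtr, y[tr], seed = seed)
        imp <- feature_importance(m1_fit)
        order(-imp, seq_along(imp))
      }, error = function(e) {
        warning("surrogate ", m1, " failed on fold ", k, ": ",
                conditionMessage(e))
        NULL
      })
      for (f in feature_sizes) for (m2 in m2_families) {
        rho <- NA_real_
        if (!is.null(ord) && f <= ncol(X)) {
          rho <- tryCatch({
            sel <- ord[seq_len(f)]
            m2_fit <- fit_family(m2, Xtr[, sel, drop = FALSE], y[tr],
                                 seed = seed)
            spearman_cor(predict(m2_fit, Xva[, sel, drop = FALSE]), y[val])
          }, error = function(e) {
            warning("cell (", m1, ", ", m2, ", ", f, ") failed on fold ", k,
                    ": ", conditionMessage(e))
            NA_real_
          })
        }
        cells[[length(cells) + 1L]] <-
          data.frame(m1 = m1, m2 = m2, f = f, fold = k, spearman = rho,
                     stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, cells)
  structure(list(cells = cells,
                 grid = list(m1_families = m1_families,
                             m2_families = m2_families,
                             feature_sizes = feature_sizes, seed = seed)),
            class = "cv_result")
}

#' Mean validation Spearman per grid cell
#'
#' @param cv A `cv_result`.
#' @return data.frame (m1, m2, f, spearman) averaging over folds.
#' @export
rho_table <- function(cv) {
  agg <- stats::aggregate(spearman ~ m1 + m2 + f, data = cv$cells,
                          FUN = mean, na.action = stats::na.pass)
  agg[order(match(agg$m1, cv$grid$m1_families),
            match(agg$m2, cv$grid$m2_families), agg$f), , drop = FALSE]
}

#' Select the best model pair
#'
#' Argmax over (m1, m2) pairs of the mean validation Spearman averaged
#' across all feature sizes; exact ties are broken by grid declaration
#' order (and logged). Pairs with no evaluated cells are skipped.
#'
#' @param cv A `cv_result`.
#' @return List with `m1`, `m2` and the pair's `mean_spearman`.
#' @export
select_model_pair <- function(cv) {
  tab <- rho_table(cv)
  pairs <- unique(tab[, c("m1", "m2")])
  pairs <- pairs[order(match(pairs$m1, cv$grid$m1_families),
                       match(pairs$m2, cv$grid$m2_families)), , drop = FALSE]
  means <- mapply(function(a, b)
    mean(tab$spearman[tab$m1 == a & tab$m2 == b], na.rm = TRUE),
    pairs$m1, pairs$m2)
  means[is.nan(means)] <- NA_real_
  if (all(is.na(means))) stop("no grid cell was evaluated successfully")
  best <- which(means == max(means, na.rm = TRUE))
  if (length(best) > 1)
    message("model-pair tie broken by declaration order: keeping (",
            pairs$m1[best[1]], ", ", pairs$m2[best[1]], ")")
  best <- best[1]
  list(m1 = pairs$m1[best], m2 = pairs$m2[best],
       mean_spearman = unname(means[best]))
}

#' Select the feature-set size via the Spearman-change rule
#'
#' Picks the smallest f in F (excluding the largest) such that increasing f
#' by one grid step improves the mean validation Spearman by no more than
#' `delta`; if no f qualifies, the largest f is returned with a message.
#'
#' @param rho_curve Named numeric vector: names are feature sizes, values
#'   the mean validation Spearman. Must have no missing values.
#' @param delta Improvement threshold (default 2e-3).
#' @return Integer f*.
#' @export
select_feature_size <- function(rho_curve, delta = 2e-3) {
  if (anyNA(rho_curve)) stop("rho curve has missing points")
  fs <- as.integer(names(rho_curve))
  if (is.null(names(rho_curve)) || anyNA(fs))
    stop("rho_curve must be named by feature sizes")
  ord <- order(fs)
  fs <- fs[ord]
  rho <- unname(rho_curve[ord])
  inc <- diff(rho)
  ok <- which(inc <= delta)
  if (!length(ok)) {
    message("no feature size satisfied the Spearman-change rule; ",
            "using max F = ", fs[length(fs)])
    return(fs[length(fs)])
  }
  fs[ok[1]]
}

#' Train the final model
#'
#' Refits the pipeline with the selected hyperparameters on the full
#' training partition and extracts the final regressor, its scaler
#' statistics (restricted to the selected features) and provenance into a
#' standalone cleavage-activity model.
#'
#' @param dataset A `nanoenv_dataset`.
#' @param split A `split_plan`.
#' @param m1,m2 Selected family names.
#' @param f Selected feature-set size.
#' @param seed Seed for the model fits.
#' @param hpr_id Optional identifier of the HPR set used at assembly.
#' @return A `sting_crispr_model`: `center`/`scale` (per selected feature),
#'   `selected_features`, `m2_model`, `provenance`.
#' @export
train_final <- function(dataset, split, m1, m2, f, seed = 1L, hpr_id = NULL) {
  tr <- split$train_rows
  pipe <- fit_pipeline(dataset$X[tr, , drop = FALSE], dataset$activity[tr],
                       m1, m2, f, seed = seed)
  idx <- pipe$selected_idx
  structure(list(center = pipe$scaler$center[idx],
                 scale = pipe$scaler$scale[idx],
                 selected_features = pipe$selected,
                 m2_model = pipe$m2_model,
                 provenance = list(m1 = m1, m2 = m2, f = f, seed = seed,
                                   n_train = length(tr), hpr_id = hpr_id)),
            class = "sting_crispr_model")
}

#' @export
print.sting_crispr_model <- function(x, ...) {
  cat("Cleavage-activity model:", x$provenance$m2, "on",
      length(x$selected_features), "features (surrogate", x$provenance$m1,
      ", trained on", x$provenance$n_train, "snapshots)\n")
  invisible(x)
}

#' Predict cleavage activity
#'
#' @param object A `sting_crispr_model`.
#' @param newdata A `nanoenv_dataset` or a numeric matrix whose columns
#'   include all selected features (raw scale).
#' @param ... Unused.
#' @return Numeric vector of predicted activities.
#' @export
predict.sting_crispr_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "nanoenv_dataset")) newdata$X else newdata
  miss <- setdiff(object$selected_features, colnames(X))
  if (length(miss))
    stop("selected feature(s) missing from newdata: ",
         paste(utils::head(miss, 5), collapse = ", "))
  Xs <- sweep(sweep(X[, object$selected_features, drop = FALSE], 2,
                    object$center, "-"), 2, object$scale, "/")
  predict(object$m2_model, Xs)
}

#' Evaluate a model on labelled data
#'
#' Computes Spearman and Pearson correlation, mean squared error and mean
#' absolute error between predicted and true activities, plus mean/sd
#' squared-error breakdowns by on-target flag, mismatch position and
#' mismatch interface type when these columns are present in `row_info`.
#'
#' @param model A `sting_crispr_model`.
#' @param dataset A `nanoenv_dataset`.
#' @param rows Row indices to evaluate (default all rows).
#' @return A `cas9_metrics` list.
#' @export
evaluate_model <- function(model, dataset, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(dataset$X))
  pred <- predict(model, dataset$X[rows, , drop = FALSE])
  truth <- dataset$activity[rows]
  se <- (pred - truth)^2
  breakdown <- function(key) {
    if (!key %in% names(dataset$row_info)) return(NULL)
    g <- dataset$row_info[[key]][rows]
    data.frame(group = tapply(se, g, length) |> names(),
               n = as.vector(tapply(se, g, length)),
               mean_se = as.vector(tapply(se, g, mean)),
               sd_se = as.vector(tapply(se, g, stats::sd)))
  }
  structure(list(spearman = spearman_cor(pred, truth),
                 pearson = stats::cor(pred, truth),
                 mse = mean(se), mae = mean(abs(pred - truth)),
                 n = length(rows),
                 by_on_target = breakdown("on_target"),
                 by_position = breakdown("position"),
                 by_interface_type = breakdown("interface_type"),
                 predictions = pred, truth = truth),
            class = "cas9_metrics")
}

#' @export
print.cas9_metrics <- function(x, ...) {
  cat(sprintf(
    "n = %d | Spearman %.3f | Pearson %.3f | MSE %.3g | MAE %.3g\n",
    x$n, x$spearman, x$pearson, x$mse, x$mae))
  invisible(x)
}

#' Trajectory-holdout cross-validation
#'
#' Generalization protocol: trajectories are sorted by activity (ties broken
#' by trajectory id, logged), and the trajectory with the nth lowest
#' activity is binned into the test partition of fold n mod 5 (folds
#' labelled fold_0..fold_4). Per fold, the chosen family is fitted on all
#' features of the training trajectories (no feature selection) and
#' Spearman/Pearson are reported on the held-out trajectories.
#'
#' @param dataset A `nanoenv_dataset`.
#' @param family A surrogate family name (default the leaf-wise GBT).
#' @param n_folds Number of folds (default 5).
#' @param seed Model seed.
#' @return data.frame with one row per fold: fold, n_test_trajectories,
#'   spearman, pearson.
#' @export
holdout_trajectory_cv <- function(dataset, family = "gbt_hist",
                                  n_folds = 5L, seed = 1L) {
  info <- dataset$row_info
  traj <- unique(info$trajectory)
  if (length(traj) < n_folds)
    stop("need at least ", n_folds, " trajectories")
  act <- dataset$activity[match(traj, info$trajectory)]
  if (anyDuplicated(act))
    message("duplicate activities: ties broken by trajectory id")
  ord <- order(act, traj)
  fold_of <- stats::setNames(seq_along(ord) %% n_folds, traj[ord])
  out <- lapply(sort(unique(fold_of)), function(k) {
    test_traj <- names(fold_of)[fold_of == k]
    te <- which(info$trajectory %in% test_traj)
    tr <- setdiff(seq_len(nrow(info)), te)
    scaler <- fit_scaler(dataset$X[tr, , drop = FALSE])
    fit <- fit_family(family, apply_scaler(dataset$X[tr, , drop = FALSE],
                                           scaler),
                      dataset$activity[tr], seed = seed)
    pred <- predict(fit, apply_scaler(dataset$X[te, , drop = FALSE], scaler))
    data.frame(fold = paste0("fold_", k),
               n_test_trajectories = length(test_traj),
               spearman = spearman_cor(pred, dataset$activity[te]),
               pearson = stats::cor(pred, dataset$activity[te]))
  })
  res <- do.call(rbind, out)
  attr(res, "fold_assignment") <- fold_of
  res
}
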