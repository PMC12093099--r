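# Shapley-value interpretation of the final cleavage-activity model:
# per-datapoint attributions, singleton and grouped importances, and
# hotspot-level (residue-cluster) reports.

#' Shapley values for a cleavage-activity model
#'
#' For boosted-tree finals the exact path-dependent tree Shapley values are
#' used (the tree library's own TreeExplainer-style `predcontrib`). For all
#' other families a seeded permutation-sampling estimator is used: for each
#' sampled permutation one background row is drawn and features are switched
#' from the background value to the explained value in permutation order;
#' the telescoping sum makes per-row additivity exact with respect to the
#' sampled base value, while the attribution itself carries Monte-Carlo
#' error of order 1/sqrt(nperm).
#'
#' @param model A `sting_crispr_model` or a bare `nanoenv_model`.
#' @param newdata A `nanoenv_dataset` or raw-scale matrix (for a
#'   `sting_crispr_model`, standardized internally with the model's training
#'   statistics), or an already-prepared matrix for a bare `nanoenv_model`.
#' @param method "auto" (tree-exact when available), "tree" or "sampling".
#' @param nperm Permutations for the sampling estimator (default 2048).
#' @param background Background matrix for the sampling estimator, on the
#'   same scale as the model input (default: the explained matrix itself).
#' @param seed Seed for the sampling estimator.
#' @return A `shap_report`: `phi` (rows x features), `base_value`,
#'   `method`, `feature_names`.
#' @export
shap_values <- function(model, newdata, method = c("auto", "tree", "sampling"),
                        nperm = 2048L, background = NULL, seed = 1L) {
  method <- match.arg(method)
  if (inherits(model, "sting_crispr_model")) {
    X <- if (inherits(newdata, "nanoenv_dataset")) newdata$X else newdata
    miss <- setdiff(model$selected_features, colnames(X))
    if (length(miss))
      stop("selected feature(s) missing from newdata: ",
           paste(utils::head(miss, 5), collapse = ", "))
    Xs <- sweep(sweep(X[, model$selected_features, drop = FALSE], 2,
                      model$center, "-"), 2, model$scale, "/")
    inner <- model$m2_model
  } else if (inherits(model, "nanoenv_model")) {
    Xs <- if (inherits(newdata, "nanoenv_dataset")) newdata$X else newdata
    inner <- model
  } else stop("unsupported model class")

  tree_exact <- inner$family %in% c("gbt", "gbt_hist")
  if (method == "tree" && !tree_exact)
    stop("exact tree Shapley is only available for the boosted-tree families")
  use_tree <- tree_exact && method != "sampling"

  if (use_tree) {
    contrib <- stats::predict(inner$fit, xgboost::xgb.DMatrix(Xs),
                              predcontrib = TRUE)
    phi <- contrib[, -ncol(contrib), drop = FALSE]
    colnames(phi) <- colnames(Xs)
    base <- contrib[1, ncol(contrib)]
    meth <- "tree"
  } else {
    if (is.null(background)) background <- Xs
    set.seed(seed)
    p <- ncol(Xs)
    n <- nrow(Xs)
    phi <- matrix(0, n, p, dimnames = list(rownames(Xs), colnames(Xs)))
    base_acc <- 0
    for (rep in seq_len(nperm)) {
      perm <- sample.int(p)
      b <- background[sample.int(nrow(background), 1L), , drop = FALSE]
      # hybrids[k,] for row i: background with features perm[1..k] from x_i
      hyb <- matrix(rep(b, each = n * (p + 1L)), n * (p + 1L), p)
      colnames(hyb) <- colnames(Xs)
      for (k in seq_len(p)) {
        js <- perm[seq_len(k)]
        rows <- seq.int(k * n + 1L, (k + 1L) * n)
        hyb[rows, js] <- Xs[, js, drop = FALSE]
      }
      pred <- predict(inner, hyb)
      predm <- matrix(pred, n, p + 1L)
      phi[, perm] <- phi[, perm] + (predm[, -1L, drop = FALSE] -
                                      predm[, -(p + 1L), drop = FALSE])
      base_acc <- base_acc + predm[1, 1]
    }
    phi <- phi / nperm
    base <- base_acc / nperm
    meth <- "sampling"
  }
  structure(list(phi = phi, base_value = base, method = meth,
                 nperm = if (meth == "sampling") nperm else NA_integer_,
                 feature_names = colnames(phi)),
            class = "shap_report")
}

#' @export
print.shap_report <- function(x, ...) {
  cat("Shapley report (", x$method, "): ", nrow(x$phi), " rows x ",
      ncol(x$phi), " features, base value ", signif(x$base_value, 4), "\n",
      sep = "")
  invisible(x)
}

as_phi <- function(x) if (inherits(x, "shap_report")) x$phi else x

#' Singleton Shapley importance
#'
#' I_j = mean over datapoints of |phi_j|. (The grouped-importance formula
#' reduces to this for singleton groups; the absolute value is essential,
#' as signed per-feature attributions average out to about zero.)
#'
#' @param phi A `shap_report` or a phi matrix.
#' @return Named numeric vector.
#' @export
singleton_importance <- function(phi) {
  phi <- as_phi(phi)
  colMeans(abs(phi))
}

#' Grouped Shapley importance
#'
#' I_J = mean over datapoints of |sum over j in J of phi_j|. Groups must be
#' disjoint; features may be left ungrouped.
#'
#' @param phi A `shap_report` or phi matrix.
#' @param groups Named list of feature-name (or index) vectors, or a factor/
#'   character vector of group labels parallel to the feature columns.
#' @return data.frame with `group`, `n_features`, `importance`.
#' @export
group_importance <- function(phi, groups) {
  phi <- as_phi(phi)
  if (!is.list(groups)) {
    groups <- split(colnames(phi), as.character(groups))
  }
  idx <- lapply(groups, function(g)
    if (is.numeric(g)) as.integer(g) else match(g, colnames(phi)))
  if (anyNA(unlist(idx))) stop("group member not found among features")
  all_idx <- unlist(idx)
  if (anyDuplicated(all_idx))
    stop("feature assigned to more than one group")
  data.frame(group = names(groups),
             n_features = lengths(idx),
             importance = vapply(idx, function(j)
               mean(abs(rowSums(phi[, j, drop = FALSE]))), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hotspot and property-grouped importance report
#'
#' Groups the final model's features by each of the six interpretive
#' properties (residue, Cas9 domain, contiguous domain, parent descriptor
#' class, descriptor class, aggregation method) and, when a residue
#' clustering is supplied, by spatial residue cluster with non-clustered
#' residues pooled into "other". Every table carries feature counts and
#' grouped Shapley importances.
#'
#' @param report A `shap_report` for the model's features.
#' @param annotations Feature annotation data.frame from
#'   [parse_feature_name()] covering every feature in the report.
#' @param clustering Optional `residue_clustering` from
#'   [cluster_residues()].
#' @return A `hotspot_report`: named list of importance data.frames keyed by
#'   grouping property (plus `residue_cluster` when clustering is given).
#' @export
hotspot_report <- function(report, annotations, clustering = NULL) {
  phi <- as_phi(report)
  feats <- colnames(phi)
  m <- match(feats, annotations$feature_name)
  if (anyNA(m))
    stop("unannotated feature(s): ",
         paste(utils::head(feats[is.na(m)], 5), collapse = ", "))
  ann <- annotations[m, , drop = FALSE]
  props <- c(residue = "residue_number", domain = "cas9_domain",
             contiguous_domain = "contiguous_domain",
             parent_class = "parent_descriptor_class",
             class = "descriptor_class", aggregation = "aggregation")
  out <- lapply(props, function(col) {
    tab <- group_importance(phi, as.character(ann[[col]]))
    tab[order(-tab$importance), , drop = FALSE]
  })
  if (!is.null(clustering)) {
    lab <- clustering$membership[as.character(ann$residue_number)]
    lab[is.na(lab)] <- "other"
    tab <- group_importance(phi, lab)
    out$residue_cluster <- tab[order(-tab$importance), , drop = FALSE]
  }
  structure(out, class = "hotspot_report")
}

#' @export
print.hotspot_report <- function(x, ...) {
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    print(x[[nm]], row.names = FALSE)
  }
  invisible(x)
}

#' Write the tables of a hotspot report as TSV files
#'
#' @param report A `hotspot_report`.
#' @param dir Output directory.
#' @return Written paths, invisibly.
#' @export
write_hotspot_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(report), function(nm) {
    p <- file.path(dir, paste0("importance_", nm, ".tsv"))
    utils::write.table(report[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }, "")
  invisible(paths)
}
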