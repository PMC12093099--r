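# Model-family registry for the three-step pipeline. Five surrogate (m1)
# families and six final (m2) families, all run with library defaults plus a
# fixed seed. Importance is |coefficient| for the linear families and
# impurity/gain importance for the tree ensembles.

#' Surrogate (m1) model families
#' @return Character vector of family names in declaration order.
#' @export
surrogate_families <- function() {
  c("linear", "ridge", "gbt", "extra_trees", "gbt_hist")
}

#' Final (m2) model families
#' @return Character vector of family names in declaration order.
#' @export
final_families <- function() {
  c(surrogate_families(), "random_forest")
}

#' Fit one model family
#'
#' Families: `linear` (minimum-norm least squares via SVD), `ridge`
#' (closed-form L2 penalty, lambda = 1, primal or dual form depending on
#' shape), `gbt` (depth-wise gradient-boosted trees, xgboost), `extra_trees`
#' (ranger, extremely randomized trees), `gbt_hist` (leaf-wise
#' histogram gradient boosting, xgboost lossguide), `random_forest`
#' (ranger). Inputs are assumed already standardized by the pipeline.
#'
#' @param family One of [final_families()].
#' @param X Numeric matrix (rows = snapshots).
#' @param y Numeric response.
#' @param seed Integer seed for the stochastic families.
#' @return A `nanoenv_model` (list with `family`, `fit`, ...).
#' @export
fit_family <- function(family, X, y, seed = 1L) {
  family <- match.arg(family, final_families())
  if (stats::sd(y) == 0 && family %in% c("gbt", "gbt_hist", "extra_trees",
                                         "random_forest"))
    warning("degenerate labels: response is constant")
  fit <- switch(
    family,
    linear = {
      ybar <- mean(y)
      sv <- svd(X)
      keep <- sv$d > max(sv$d[1], 0) * 1e-10
      coef <- sv$v[, keep, drop = FALSE] %*%
        (crossprod(sv$u[, keep, drop = FALSE], y - ybar) / sv$d[keep])
      list(coef = drop(coef), intercept = ybar)
    },
    ridge = {
      lambda <- 1
      ybar <- mean(y)
      yc <- y - ybar
      coef <- if (ncol(X) <= nrow(X)) {
        solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, yc))
      } else {
        crossprod(X, solve(tcrossprod(X) + lambda * diag(nrow(X)), yc))
      }
      list(coef = drop(coef), intercept = ybar)
    },
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(params = list(objective = "reg:squarederror",
                                       eta = 0.3, max_depth = 6,
                                       nthread = 1, seed = seed),
                         dtrain, nrounds = 100, verbose = 0)
    },
    gbt_hist = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(params = list(objective = "reg:squarederror",
                                       tree_method = "hist",
                                       grow_policy = "lossguide",
                                       max_leaves = 31, max_depth = 0,
                                       eta = 0.1, nthread = 1, seed = seed),
                         dtrain, nrounds = 100, verbose = 0)
    },
    extra_trees = ranger::ranger(
      x = as.data.frame(X), y = y, num.trees = 100, mtry = ncol(X),
      splitrule = "extratrees", num.random.splits = 1, replace = FALSE,
      sample.fraction = 1, importance = "impurity", seed = seed,
      num.threads = 1),
    random_forest = ranger::ranger(
      x = as.data.frame(X), y = y, importance = "impurity", seed = seed,
      num.threads = 1))
  structure(list(family = family, fit = fit, feature_names = colnames(X),
                 p = ncol(X), seed = seed),
            class = "nanoenv_model")
}

#' Predict from a fitted model family
#'
#' @param object A `nanoenv_model`.
#' @param newdata Numeric matrix with the same columns as at fit time.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.nanoenv_model <- function(object, newdata, ...) {
  switch(object$family,
         linear = ,
         ridge = drop(newdata %*% object$fit$coef) + object$fit$intercept,
         gbt = ,
         gbt_hist = stats::predict(object$fit, xgboost::xgb.DMatrix(newdata)),
         extra_trees = ,
         random_forest =
           stats::predict(object$fit, data = as.data.frame(newdata),
                          num.threads = 1)$predictions)
}

#' Feature importance of a fitted model family
#'
#' Absolute coefficients for the linear families; gain importance for the
#' boosted trees (features never used score 0); impurity importance for the
#' ranger ensembles.
#'
#' @param model A `nanoenv_model`.
#' @return Named numeric vector over all fitted features.
#' @export
feature_importance <- function(model) {
  nm <- model$feature_names
  if (is.null(nm)) nm <- paste0("V", seq_len(model$p))
  switch(model$family,
         linear = ,
         ridge = stats::setNames(abs(model$fit$coef), nm),
         gbt = ,
         gbt_hist = {
           imp <- xgboost::xgb.importance(model = model$fit)
           out <- stats::setNames(numeric(length(nm)), nm)
           out[imp$Feature] <- imp$Gain
           out
         },
         extra_trees = ,
         random_forest = {
           v <- model$fit$variable.importance
           stats::setNames(as.numeric(v)[match(nm, names(v))], nm)
         })
}
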