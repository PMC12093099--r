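test_that("exact tree Shapley matches subset enumeration on stump ensembles", {
  d <- std_dataset()
  # depth-1 trees: path-dependent and interventional Shapley coincide
  dm <- xgboost::xgb.DMatrix(d$X, label = d$y)
  fit <- xgboost::xgb.train(params = list(objective = "reg:squarederror",
                                          max_depth = 1, eta = 0.5,
                                          nthread = 1, seed = 1),
                            dm, nrounds = 20, verbose = 0)
  model <- structure(list(family = "gbt", fit = fit,
                          feature_names = colnames(d$X), p = 3L),
                     class = "nanoenv_model")
  rep <- shap_values(model, d$X)
  expect_equal(rep$method, "tree")
  pf <- function(M) predict(fit, xgboost::xgb.DMatrix(M))
  for (i in c(1, 9, 32)) {
    phi_bf <- brute_force_shapley(pf, d$X[i, ], d$X)
    expect_equal(unname(rep$phi[i, ]), phi_bf, tolerance = 1e-5)
  }
  # additivity to 1e-6 on every row
  pred <- pf(d$X)
  expect_lt(max(abs(rowSums(rep$phi) + rep$base_value - pred)), 1e-6)
})

test_that("sampling Shapley agrees with enumeration within Monte-Carlo tolerance", {
  d <- std_dataset(n = 24)
  fit <- fit_family("extra_trees", d$X, d$y, seed = 1)
  rep <- shap_values(fit, d$X, method = "sampling", nperm = 3000L, seed = 7)
  pf <- function(M) predict(fit, M)
  for (i in c(2, 17)) {
    phi_bf <- brute_force_shapley(pf, d$X[i, ], d$X)
    expect_equal(unname(rep$phi[i, ]), phi_bf, tolerance = 0.05)
  }
  # telescoping makes additivity exact against the sampled base value
  expect_lt(max(abs(rowSums(rep$phi) + rep$base_value - pf(d$X))), 1e-10)
})

test_that("a constant model yields zero attributions and the constant base", {
  d <- std_dataset()
  const <- structure(list(family = "linear",
                          fit = list(coef = rep(0, 3), intercept = 0.7),
                          feature_names = colnames(d$X), p = 3L),
                     class = "nanoenv_model")
  rep <- shap_values(const, d$X, nperm = 50L, seed = 1)
  expect_true(all(rep$phi == 0))
  expect_equal(rep$base_value, 0.7)
})

test_that("singleton importance is the mean absolute attribution", {
  phi <- rbind(c(0.3, 0, -0.1), c(-0.3, 0, 0.5))
  colnames(phi) <- paste0("f", 1:3)
  I <- singleton_importance(phi)
  expect_equal(unname(I), c(0.3, 0, 0.3))
  expect_equal(singleton_importance(phi[c(2, 1), ]), I)  # row-permutation
})

test_that("grouped importance cancels opposing attributions and keeps counts", {
  phi <- cbind(f1 = c(0.2, 0.2), f2 = c(-0.2, -0.2), f3 = c(0.1, -0.1))
  g <- group_importance(phi, list(AB = c("f1", "f2"), C = "f3"))
  expect_equal(g$importance[g$group == "AB"], 0)  # +a and -a cancel
  expect_equal(g$importance[g$group == "C"], 0.1)
  expect_equal(g$n_features, c(2L, 1L))
  # singleton groups reduce to singleton importance
  gs <- group_importance(phi, list(f1 = "f1", f2 = "f2", f3 = "f3"))
  expect_equal(gs$importance, unname(singleton_importance(phi)))
  # 3-feature toy checked against the direct formula
  direct <- mean(abs(phi[, "f1"] + phi[, "f3"]))
  g2 <- group_importance(phi, list(AC = c("f1", "f3"), B = "f2"))
  expect_equal(g2$importance[g2$group == "AC"], direct)
  expect_error(group_importance(phi, list(a = c("f1", "f2"), b = "f2")),
               "more than one group")
})

test_that("group importance satisfies the triangle inequality on random reports", {
  set.seed(5)
  for (rep in 1:10) {
    phi <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("f", 1:5)))
    grp <- sample(c("a", "b"), 5, replace = TRUE)
    gi <- group_importance(phi, grp)
    si <- singleton_importance(phi)
    for (g in gi$group) {
      expect_lte(gi$importance[gi$group == g],
                 sum(si[grp == g]) + 1e-12)
    }
    expect_equal(sum(gi$n_features), 5L)
  }
})

test_that("hotspot report groups features by all six properties and by cluster", {
  cfg <- tiny_config(noise_sd = 0.05)
  # informative features confined to residues 1 and 2 (adjacent in space)
  truth_res <- rep(c(1L, 2L), 2)
  truth_desc <- descriptor_names(8)[c(1, 2, 1, 2)]
  td <- tiny_dataset(cfg, residues = truth_res, descriptors = truth_desc)
  ds <- td$dataset
  sp <- make_split(ds, n_holdout = 2L, cv_seed = 1L)
  model <- train_final(ds, sp, "ridge", "gbt", 6L, seed = 1L)
  rep <- shap_values(model, ds)
  ann <- parse_feature_name(model$selected_features)
  flat <- unlist(td$sim$snapshots, recursive = FALSE)
  res <- sort(unique(ann$residue_number))
  clustering <- cluster_residues(
    mean_pairwise_residue_distances(flat, res), cutoff = 12)
  hs <- hotspot_report(rep, ann, clustering)
  expect_named(hs, c("residue", "domain", "contiguous_domain", "parent_class",
                     "class", "aggregation", "residue_cluster"))
  for (tab in hs) expect_equal(sum(tab$n_features),
                               length(model$selected_features))
  # the planted-residue cluster dominates the grouped importance
  rc <- hs$residue_cluster
  planted_grp <- clustering$membership["1"]
  expect_equal(rc$group[which.max(rc$importance)], unname(planted_grp))
  expect_error(hotspot_report(rep, ann[-1, ], clustering), "unannotated")
})

test_that("all features on one residue collapse to a single group", {
  phi <- cbind(Cas9_10_accessibility = c(0.1, 0.2),
               Cas9_10_dssp = c(0.05, -0.05))
  ann <- parse_feature_name(colnames(phi))
  hs <- hotspot_report(phi, ann)
  expect_equal(nrow(hs$residue), 1L)
  expect_equal(hs$residue$n_features, 2L)
})
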