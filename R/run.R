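# End-to-end driver tying the modules together: simulate (optional) ->
# parse -> HPR -> assemble -> split -> grid search -> selection rules ->
# final training -> evaluation -> interpretation -> stability. Every
# artifact is stamped with the configuration hash and seeds via a manifest.

#' Build a run configuration
#'
#' Either `synthetic` is a [synthetic_config()] (the generator supplies the
#' study), or `snapshots_dir`, `descriptor_tsv` and `labels_tsv` point to
#' on-disk inputs. Numeric parameters default to the study conditions.
#'
#' @param output_dir Directory for artifacts.
#' @param synthetic Optional [synthetic_config()].
#' @param snapshots_dir,descriptor_tsv,labels_tsv Input paths (ignored when
#'   `synthetic` is given).
#' @param chain_map See [default_chain_map()].
#' @param d_min,d_max HPR distance bounds (Angstrom).
#' @param n_holdout Test snapshots held out per trajectory.
#' @param m1_families,m2_families,feature_sizes Grid definition.
#' @param delta_rho Spearman-change threshold for the feature-size rule.
#' @param cluster_cutoff Hotspot clustering cutoff (Angstrom).
#' @param cv_seed,model_seed Seeds for fold assignment and model fits.
#' @param shap_nperm Permutations for the sampling Shapley estimator when
#'   the final model has no exact tree explainer.
#' @param stability_sites Number of top-importance residues carried into
#'   the stability stage.
#' @return A `run_config` list.
#' @export
run_config <- function(output_dir,
                       synthetic = NULL,
                       snapshots_dir = NULL, descriptor_tsv = NULL,
                       labels_tsv = NULL,
                       chain_map = default_chain_map(),
                       d_min = 3, d_max = 7, n_holdout = 4L,
                       m1_families = surrogate_families(),
                       m2_families = final_families(),
                       feature_sizes = seq(5L, 50L, by = 5L),
                       delta_rho = 2e-3, cluster_cutoff = 12,
                       cv_seed = 1L, model_seed = 1L, shap_nperm = 256L,
                       stability_sites = 5L) {
  cfg <- list(output_dir = output_dir, synthetic = synthetic,
              snapshots_dir = snapshots_dir, descriptor_tsv = descriptor_tsv,
              labels_tsv = labels_tsv, chain_map = chain_map,
              d_min = d_min, d_max = d_max, n_holdout = as.integer(n_holdout),
              m1_families = m1_families, m2_families = m2_families,
              feature_sizes = as.integer(feature_sizes),
              delta_rho = delta_rho, cluster_cutoff = cluster_cutoff,
              cv_seed = as.integer(cv_seed),
              model_seed = as.integer(model_seed),
              shap_nperm = as.integer(shap_nperm),
              stability_sites = as.integer(stability_sites))
  if (is.null(synthetic)) {
    for (p in c("snapshots_dir", "descriptor_tsv", "labels_tsv"))
      if (is.null(cfg[[p]]) || !file.exists(cfg[[p]]))
        stop("missing input path for ", p, ": ",
             if (is.null(cfg[[p]])) "(not set)" else cfg[[p]])
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(config) {
  keep <- config[setdiff(names(config), "output_dir")]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full analysis workflow
#'
#' Executes every stage of the nanoenvironment workflow and writes the
#' artifacts (HPR list, CV table, selected features, metrics JSON,
#' importance tables, clustering JSON, stability table, manifest) under
#' `config$output_dir`. Any stage error aborts with the stage name; already
#' written artifacts are preserved.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (!is.null(config$synthetic)) {
    sim <- stage("simulate", synthetic_dataset(config$synthetic))
    snapshots <- sim$snapshots
    table <- sim$table
    labels <- sim$activities
  } else {
    snapshots <- stage("parse",
                       read_snapshot_dir(config$snapshots_dir, config$chain_map))
    table <- stage("parse", parse_descriptor_tsv(config$descriptor_tsv))
    labels <- stage("parse", utils::read.table(config$labels_tsv,
                                               header = TRUE, sep = "\t"))
  }

  flat <- flatten_snapshots(snapshots)
  snap_ids <- vapply(flat, function(s) s$snapshot_id, "")
  snap_no <- vapply(snap_ids, function(s) parse_snapshot_id(s)$snapshot_number,
                    0L)
  traj_of <- vapply(flat, function(s) s$trajectory_id, "")
  is_test <- stats::ave(snap_no, traj_of, FUN = function(v)
    rank(v) > length(v) - config$n_holdout) > 0

  hpr <- stage("hpr", compute_hpr_set(flat[!is_test], config$d_min,
                                      config$d_max))
  utils::write.table(hpr$residues, file.path(out, "hpr_residues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, "hpr_residues.tsv")

  dataset <- stage("assemble", assemble_matrix(table, hpr, labels))
  split <- stage("split", make_split(dataset, config$n_holdout,
                                     config$cv_seed))
  cv <- stage("gridsearch",
              grid_search(dataset, split, config$m1_families,
                          config$m2_families, config$feature_sizes,
                          seed = config$model_seed))
  utils::write.table(cv$cells, file.path(out, "cv_cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, "cv_cells.tsv")

  pair <- stage("select", select_model_pair(cv))
  tab <- rho_table(cv)
  curve <- tab[tab$m1 == pair$m1 & tab$m2 == pair$m2, ]
  fstar <- stage("select", select_feature_size(
    stats::setNames(curve$spearman, curve$f), config$delta_rho))

  model <- stage("train", train_final(dataset, split, pair$m1, pair$m2,
                                      fstar, seed = config$model_seed))
  utils::write.table(data.frame(feature = model$selected_features),
                     file.path(out, "selected_features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, "selected_features.tsv")

  metrics <- stage("evaluate", evaluate_model(model, dataset,
                                              split$test_rows))
  write_json_artifact(
    list(config_hash = config_hash(config),
         m1 = pair$m1, m2 = pair$m2, f = fstar,
         cv_mean_spearman = pair$mean_spearman,
         test = metrics[c("spearman", "pearson", "mse", "mae", "n")]),
    file.path(out, "metrics.json"))
  artifacts <- c(artifacts, "metrics.json")

  interp <- stage("interpret", {
    rep <- shap_values(model, dataset, nperm = config$shap_nperm,
                       seed = config$model_seed)
    ann <- parse_feature_name(model$selected_features)
    res <- sort(unique(ann$residue_number))
    clustering <- if (length(res) >= 2)
      cluster_residues(mean_pairwise_residue_distances(flat, res),
                       config$cluster_cutoff) else NULL
    hs <- hotspot_report(rep, ann, clustering)
    list(shap = rep, clustering = clustering, report = hs)
  })
  write_hotspot_report(interp$report, out)
  artifacts <- c(artifacts, paste0("importance_", names(interp$report),
                                   ".tsv"))
  if (!is.null(interp$clustering)) {
    write_json_artifact(
      list(cutoff = interp$clustering$cutoff,
           clusters = interp$clustering$clusters,
           other = interp$clustering$singletons),
      file.path(out, "residue_clusters.json"))
    artifacts <- c(artifacts, "residue_clusters.json")
  }

  stab <- stage("stability", {
    imp <- singleton_importance(interp$shap)
    ann <- parse_feature_name(names(imp))
    by_res <- sort(tapply(imp, ann$residue_number, sum), decreasing = TRUE)
    sites <- utils::head(as.integer(names(by_res)), config$stability_sites)
    ref_traj <- traj_of[1]
    per_traj <- split(seq_along(flat), traj_of)
    ref_frames <- lapply(flat[per_traj[[ref_traj]]], snapshot_frame)
    rows <- lapply(setdiff(names(per_traj), ref_traj), function(tr) {
      frames <- lapply(flat[per_traj[[tr]]], snapshot_frame)
      st <- stability_table(frames, ref_frames,
                            sites = lapply(sites, function(r)
                              list(chain = "A", resno = r)),
                            atom_selection = "calpha")
      cbind(trajectory = tr, st)
    })
    do.call(rbind, rows)
  })
  utils::write.table(stab, file.path(out, "stability.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, "stability.tsv")

  write_json_artifact(
    list(config_hash = config_hash(config),
         seeds = list(synthetic = if (!is.null(config$synthetic))
           config$synthetic$seed, cv = config$cv_seed,
           model = config$model_seed),
         inputs = if (is.null(config$synthetic))
           list(snapshots_dir = config$snapshots_dir,
                descriptor_tsv = config$descriptor_tsv,
                labels_tsv = config$labels_tsv) else "synthetic",
         artifacts = artifacts),
    file.path(out, "manifest.json"))

  invisible(list(hpr = hpr, dataset = dataset, split = split, cv = cv,
                 pair = pair, f = fstar, model = model, metrics = metrics,
                 interpret = interp, stability = stab))
}

# Convert a cas9_snapshot (Calpha + C4' pseudo-atoms) into the atom-table
# frame format consumed by rmsd_series().
snapshot_frame <- function(snapshot) {
  r <- snapshot$residues
  n <- snapshot$nucleotides
  rbind(data.frame(chain = r$chain, resno = r$resno, resid = r$resname,
                   elety = "CA", x = r$x, y = r$y, z = r$z),
        data.frame(chain = ifelse(n$strand == "sgRNA", "B", "C"),
                   resno = n$position, resid = n$base, elety = "C4'",
                   x = n$x, y = n$y, z = n$z))
}
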