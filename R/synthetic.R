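#' Configuration for the synthetic nanoenvironment study generator
#'
#' Defines a toy sgRNA-dsDNA-Cas9 study: a set of MD-like trajectories, each a
#' jittered copy of one template structure, plus a long-format descriptor table
#' in which a small planted set of (residue, descriptor) features carries a
#' trajectory-level latent signal that also determines the cleavage-activity
#' label. Defaults reproduce the study scale: 28 trajectories x 24 snapshots
#' (672 conformations), a 20-bp heteroduplex ladder, 40 heteroduplex-proximal
#' residues x 50 descriptors (2,000 candidate features) of which 20 are
#' informative with unit weights at a per-feature signal-to-noise ratio of 3.
#'
#' All randomness flows from `seed` through fixed per-stage substreams:
#' snapshot jitter uses `seed + 1`, planted-feature placement `seed + 2`,
#' trajectory latents `seed + 3`, label noise `seed + 4`, descriptor noise
#' `seed + 5`. Two calls with the same seed are bit-identical.
#'
#' @param n_trajectories Number of trajectories (complexes).
#' @param n_snapshots_per_trajectory Snapshots sampled per trajectory.
#' @param n_residues Total protein residues in the template.
#' @param n_proximal_residues Residues placed with Calpha 3-7 Angstrom from
#'   some heteroduplex C4' atom in the jitter-free template (residue numbers
#'   `1..n_proximal_residues`); the remainder are placed > 9 Angstrom away.
#' @param n_descriptors Number of descriptor columns in the long table.
#' @param n_informative_features Number of planted (residue, descriptor)
#'   features carrying the activity signal.
#' @param informative_weights Weight vector for the planted features
#'   (recycled to length `n_informative_features`).
#' @param noise_sd Gaussian noise sd added to informative feature values
#'   (non-informative features are pure standard normal noise).
#' @param label_noise_sd Gaussian noise sd on the activity labels.
#' @param jitter_sd Per-snapshot Gaussian coordinate jitter sd in Angstrom.
#' @param activity_intercept,activity_slope Affine map from the normalised
#'   latent score to activity before clipping to `[0, 1]`.
#' @param seed Integer master seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_trajectories = 28L,
                             n_snapshots_per_trajectory = 24L,
                             n_residues = 60L,
                             n_proximal_residues = 40L,
                             n_descriptors = 50L,
                             n_informative_features = 20L,
                             informative_weights = 1,
                             noise_sd = 1 / 3,
                             label_noise_sd = 0.01,
                             jitter_sd = 0.3,
                             activity_intercept = 0.5,
                             activity_slope = 0.15,
                             seed = 1L) {
  counts <- c(n_trajectories = n_trajectories,
              n_snapshots_per_trajectory = n_snapshots_per_trajectory,
              n_residues = n_residues, n_proximal_residues = n_proximal_residues,
              n_descriptors = n_descriptors)
  if (any(counts < 1))
    stop("configuration error: counts must be positive: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  if (n_informative_features < 0)
    stop("configuration error: n_informative_features must be >= 0")
  if (n_proximal_residues > n_residues)
    stop("configuration error: n_proximal_residues exceeds n_residues")
  if (n_informative_features > n_proximal_residues * n_descriptors)
    stop("configuration error: n_informative_features exceeds ",
         "n_proximal_residues * n_descriptors")
  sds <- c(noise_sd = noise_sd, label_noise_sd = label_noise_sd,
           jitter_sd = jitter_sd)
  if (any(sds < 0))
    stop("configuration error: negative sd: ",
         paste(names(sds)[sds < 0], collapse = ", "))
  if (n_snapshots_per_trajectory > 99L)
    stop("configuration error: snapshot numbers are two digits (max 99)")
  if (n_trajectories > 36L)
    stop("configuration error: mutation codes are one of 0-9A-Z (max 36)")
  weights <- rep_len(as.numeric(informative_weights), n_informative_features)
  structure(list(
    n_trajectories = as.integer(n_trajectories),
    n_snapshots_per_trajectory = as.integer(n_snapshots_per_trajectory),
    n_residues = as.integer(n_residues),
    n_proximal_residues = as.integer(n_proximal_residues),
    n_descriptors = as.integer(n_descriptors),
    n_informative_features = as.integer(n_informative_features),
    informative_weights = weights,
    noise_sd = noise_sd, label_noise_sd = label_noise_sd,
    jitter_sd = jitter_sd,
    activity_intercept = activity_intercept, activity_slope = activity_slope,
    seed = as.integer(seed)), class = "synthetic_config")
}

# Heteroduplex template: two parallel straight strands of C4' pseudo-atoms,
# 6 A apart in x, 5 A rise per position along z. Position +1 (PAM-proximal)
# sits at z = 0, +20 (PAM-distal) at z = 95.
template_nucleotides <- function() {
  pos <- 1:20
  rna_bases <- rep(c("A", "C", "G", "U"), 5)
  dna_bases <- c(A = "DT", C = "DG", G = "DC", U = "DA")[rna_bases]
  rbind(
    data.frame(strand = "sgRNA", position = pos, base = rna_bases,
               x = 0, y = 0, z = 5 * (pos - 1)),
    data.frame(strand = "tsDNA", position = pos, base = unname(dna_bases),
               x = 6, y = 0, z = 5 * (pos - 1)))
}

# Proximal residue j sits at (0, -d_j, z of its anchor nucleotide) so its
# nearest-C4' distance is exactly d_j in [3.2, 6.8]; distal residues sit on a
# rail at x = -15 (>= 15 A from every C4').
template_residues <- function(config) {
  n <- config$n_residues
  np <- config$n_proximal_residues
  nt <- template_nucleotides()
  rna_z <- nt$z[nt$strand == "sgRNA"]
  res <- data.frame(chain = "A", resno = seq_len(n), resname = "ALA",
                    x = 0, y = 0, z = 0)
  if (np > 0) {
    anchor <- ((seq_len(np) - 1L) %% 20L) + 1L
    d <- if (np == 1) 5 else 3.2 + 3.6 * (seq_len(np) - 1) / (np - 1)
    res$x[seq_len(np)] <- 0
    res$y[seq_len(np)] <- -d
    res$z[seq_len(np)] <- rna_z[anchor]
  }
  if (np < n) {
    k <- seq_len(n - np)
    res$x[np + k] <- -15
    res$y[np + k] <- 0
    res$z[np + k] <- 95 * (k - 1) / max(1, length(k) - 1)
  }
  res
}

trajectory_ids <- function(config) {
  codes <- strsplit("0123456789ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1]]
  paste0("C", codes[seq_len(config$n_trajectories)])
}

#' Generate synthetic trajectory snapshots
#'
#' Builds the jitter-free template (a 20-pair C4' ladder plus the residue
#' cloud) and emits, per trajectory, `n_snapshots_per_trajectory` snapshots
#' equal to the template plus i.i.d. Gaussian coordinate jitter of sd
#' `jitter_sd`. Snapshot identifiers follow the four-character naming scheme
#' (see [parse_snapshot_id()]).
#'
#' @param config A [synthetic_config()].
#' @return Named list (one element per trajectory) of lists of
#'   `cas9_snapshot` objects.
#' @export
generate_snapshots <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  res <- template_residues(config)
  nt <- template_nucleotides()
  set.seed(config$seed + 1L)
  traj <- trajectory_ids(config)
  out <- lapply(traj, function(tid) {
    lapply(seq_len(config$n_snapshots_per_trajectory), function(s) {
      r <- res; n <- nt
      if (config$jitter_sd > 0) {
        r[, c("x", "y", "z")] <- r[, c("x", "y", "z")] +
          matrix(stats::rnorm(3 * nrow(r), 0, config$jitter_sd), ncol = 3)
        n[, c("x", "y", "z")] <- n[, c("x", "y", "z")] +
          matrix(stats::rnorm(3 * nrow(n), 0, config$jitter_sd), ncol = 3)
      }
      structure(list(snapshot_id = sprintf("%s%02d", tid, s),
                     trajectory_id = tid, residues = r, nucleotides = n),
                class = "cas9_snapshot")
    })
  })
  names(out) <- traj
  out
}

#' Planted ground truth for the synthetic generator
#'
#' Chooses which (residue, descriptor) features carry the activity signal.
#' By default the pairs are sampled (seeded, substream `seed + 2`) from the
#' proximal-residue x descriptor grid; explicit `residues`/`descriptors`
#' vectors (parallel, one entry per feature) override the sampling, which is
#' how tests confine informative features to chosen spatial hotspots.
#'
#' @param config A [synthetic_config()].
#' @param residues,descriptors Optional parallel vectors of residue numbers
#'   and descriptor names naming the informative features explicitly.
#' @return Object of class `planted_truth` with `features` (data.frame:
#'   residue, descriptor), `weights` and the activity-function tag.
#' @export
planted_truth <- function(config, residues = NULL, descriptors = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  desc_names <- descriptor_names(config$n_descriptors)
  if (is.null(residues) != is.null(descriptors))
    stop("residues and descriptors must be given together")
  if (!is.null(residues)) {
    stopifnot(length(residues) == length(descriptors))
    feats <- data.frame(residue = as.integer(residues),
                        descriptor = as.character(descriptors))
    if (nrow(feats) != config$n_informative_features)
      stop("explicit truth must list n_informative_features features")
  } else {
    set.seed(config$seed + 2L)
    grid_n <- config$n_proximal_residues * config$n_descriptors
    idx <- sample.int(grid_n, config$n_informative_features)
    feats <- data.frame(
      residue = ((idx - 1L) %% config$n_proximal_residues) + 1L,
      descriptor = desc_names[((idx - 1L) %/% config$n_proximal_residues) + 1L])
  }
  structure(list(features = feats, weights = config$informative_weights,
                 activity_function = "affine-clipped to [0,1]"),
            class = "planted_truth")
}

# One latent signal per trajectory (substream seed + 3): the label is a
# trajectory property, mirroring one experimental activity per complex.
trajectory_latents <- function(config) {
  set.seed(config$seed + 3L)
  stats::setNames(stats::rnorm(config$n_trajectories), trajectory_ids(config))
}

#' Generate per-trajectory activity labels
#'
#' activity = clip(intercept + slope * u + N(0, label_noise_sd), 0, 1) where
#' u is the weight-normalised latent score sum(w_j) * z_t / max(1, sum|w_j|).
#' Every snapshot of a trajectory shares its trajectory's label.
#'
#' @param truth A [planted_truth()].
#' @param config A [synthetic_config()].
#' @return data.frame with columns `trajectory`, `activity`.
#' @export
generate_activities <- function(truth, config) {
  stopifnot(inherits(truth, "planted_truth"), inherits(config, "synthetic_config"))
  z <- trajectory_latents(config)
  u <- sum(truth$weights) * z / max(1, sum(abs(truth$weights)))
  set.seed(config$seed + 4L)
  eps <- if (config$label_noise_sd > 0)
    stats::rnorm(length(z), 0, config$label_noise_sd) else 0
  a <- pmin(pmax(config$activity_intercept + config$activity_slope * u + eps, 0), 1)
  data.frame(trajectory = names(z), activity = unname(a))
}

#' Generate the long-format descriptor table
#'
#' One record per (snapshot, residue, descriptor). A planted feature (r, d)
#' with weight w takes value w * z_t + N(0, noise_sd) in every snapshot of
#' trajectory t; all other features are standard normal noise (substream
#' `seed + 5`).
#'
#' @param snapshots Output of [generate_snapshots()].
#' @param truth A [planted_truth()].
#' @param config A [synthetic_config()].
#' @return data.frame with columns `snapshot`, `residue`, `descriptor`,
#'   `value` (a `DescriptorTable` in long form).
#' @export
generate_descriptor_table <- function(snapshots, truth, config) {
  stopifnot(length(snapshots) > 0)
  snaps <- unlist(lapply(snapshots, function(tr)
    vapply(tr, function(s) s$snapshot_id, "")), use.names = FALSE)
  traj_of <- substr(snaps, 1L, 2L)
  desc <- descriptor_names(config$n_descriptors)
  res <- seq_len(config$n_residues)
  # layout: residue fastest, then descriptor, then snapshot
  rec <- expand.grid(residue = res, descriptor = desc, snapshot = snaps,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  z <- trajectory_latents(config)
  set.seed(config$seed + 5L)
  value <- stats::rnorm(nrow(rec))
  key <- paste(rec$residue, rec$descriptor)
  tkey <- paste(truth$features$residue, truth$features$descriptor)
  hit <- match(key, tkey)
  inf <- !is.na(hit)
  signal <- truth$weights[hit[inf]] * z[traj_of[match(rec$snapshot[inf], snaps)]]
  noise <- if (config$noise_sd > 0)
    stats::rnorm(sum(inf), 0, config$noise_sd) else 0
  value[inf] <- signal + noise
  rec$value <- value
  rec[, c("snapshot", "residue", "descriptor", "value")]
}

#' Descriptor name vocabulary used by the generator
#'
#' Names follow the feature-name schema consumed by [parse_feature_name()]:
#' a descriptor slug (neighbour descriptors carry a shell radius) plus an
#' optional trailing aggregation token (GN, SW, WNA or VD).
#'
#' @param n Number of distinct descriptor names.
#' @return Character vector of length `n`.
#' @export
descriptor_names <- function(n) {
  parents_plain <- c("accessibility", "dssp", "hydrophobicity", "stride")
  parents_nb <- c("density", "side_chain_angle", "electrostatic_potential",
                  "entropy_density", "sponge", "cross_presence_order",
                  "contact_energy_density", "graph_descriptor", "solvation",
                  "curvature", "cross_link_order", "residue_contacts",
                  "unused_contacts", "weighted_contact_number")
  aggs <- c("GN", "SW", "WNA", "VD")
  radii <- c(3, 5, 12)
  base <- c(parents_plain,
            as.vector(outer(as.vector(outer(
              paste0("neighbours_", parents_nb), radii, paste, sep = "_")),
              aggs, paste, sep = "_")))
  if (n <= length(base)) return(base[seq_len(n)])
  extra <- paste0("neighbours_density_", seq_len(n - length(base)) + 100, "_SW")
  c(base, extra)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [planted_truth()], [generate_snapshots()],
#' [generate_activities()] and [generate_descriptor_table()] in that order.
#'
#' @inheritParams planted_truth
#' @return List with `config`, `truth`, `snapshots`, `activities`, `table`.
#' @export
synthetic_dataset <- function(config, residues = NULL, descriptors = NULL) {
  truth <- planted_truth(config, residues, descriptors)
  snapshots <- generate_snapshots(config)
  activities <- generate_activities(truth, config)
  table <- generate_descriptor_table(snapshots, truth, config)
  list(config = config, truth = truth, snapshots = snapshots,
       activities = activities, table = table)
}

#' Write a snapshot as a minimal PDB file
#'
#' Emits ATOM records only: protein Calpha atoms (chain A) and heteroduplex
#' C4' pseudo-atoms (sgRNA chain B, tsDNA chain C; residue number equals
#' heteroduplex position).
#'
#' @param snapshot A `cas9_snapshot`.
#' @param path Output file path.
#' @param chain_map Chain role assignment, see [default_chain_map()].
#' @return `path`, invisibly.
#' @export
write_snapshot_pdb <- function(snapshot, path, chain_map = default_chain_map()) {
  r <- snapshot$residues
  n <- snapshot$nucleotides
  strand_chain <- c(sgRNA = chain_map$sgRNA, tsDNA = chain_map$tsDNA)
  lines <- character(nrow(r) + nrow(n))
  # fixed PDB columns: serial 7-11, name 13-16, resName 18-20, chain 22,
  # resSeq 23-26, x/y/z 31-54
  fmt <- "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  i <- 0L
  for (k in seq_len(nrow(r))) {
    i <- i + 1L
    lines[i] <- sprintf(fmt, i, " CA ", r$resname[k], chain_map$protein,
                        r$resno[k], r$x[k], r$y[k], r$z[k], 1, 0, "C")
  }
  for (k in seq_len(nrow(n))) {
    i <- i + 1L
    lines[i] <- sprintf(fmt, i, " C4'", n$base[k],
                        strand_chain[[n$strand[k]]], n$position[k],
                        n$x[k], n$y[k], n$z[k], 1, 0, "C")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write all snapshots of a study to a directory
#'
#' One file per snapshot, named `<snapshot_id>.pdb`.
#'
#' @param snapshots Output of [generate_snapshots()].
#' @param dir Output directory (created if absent).
#' @param chain_map See [default_chain_map()].
#' @return Character vector of written paths, invisibly.
#' @export
write_snapshots <- function(snapshots, dir, chain_map = default_chain_map()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- unlist(lapply(snapshots, function(tr) vapply(tr, function(s) {
    p <- file.path(dir, paste0(s$snapshot_id, ".pdb"))
    write_snapshot_pdb(s, p, chain_map)
    p
  }, "")), use.names = FALSE)
  invisible(paths)
}

#' Write per-trajectory activity labels as TSV
#'
#' @param activities data.frame with `trajectory`, `activity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_tsv <- function(activities, path) {
  utils::write.table(activities, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
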