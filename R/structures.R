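#' Default chain role assignment
#'
#' Maps PDB chain identifiers to their roles in the sgRNA-dsDNA-Cas9 complex
#' (protein, sgRNA, tsDNA) and optionally maps nucleic residue numbers to
#' heteroduplex positions. With `position_map = NULL` the residue number is
#' the heteroduplex position itself (+1 PAM-proximal ... +20 PAM-distal).
#'
#' @param protein,sgRNA,tsDNA Chain IDs.
#' @param position_map Optional data.frame with columns `chain`, `resno`,
#'   `position` overriding the identity numbering.
#' @return A list usable as `chain_map` throughout the package.
#' @export
default_chain_map <- function(protein = "A", sgRNA = "B", tsDNA = "C",
                              position_map = NULL) {
  list(protein = protein, sgRNA = sgRNA, tsDNA = tsDNA,
       position_map = position_map)
}

#' Parse a PDB snapshot
#'
#' Reads a structure file with [bio3d::read.pdb()] and extracts protein
#' Calpha atoms and heteroduplex C4' atoms according to the chain map.
#' Alternate locations other than blank or 'A' are skipped with a warning.
#'
#' @param path Path to a PDB file.
#' @param chain_map See [default_chain_map()].
#' @param snapshot_id Four-character snapshot identifier; default is the file
#'   base name.
#' @param trajectory_id Trajectory identifier; default is derived from the
#'   snapshot id via [parse_snapshot_id()] when it is four characters.
#' @return A `cas9_snapshot` with `residues` (chain, resno, resname, x, y, z)
#'   and `nucleotides` (strand, position, base, x, y, z).
#' @export
parse_snapshot <- function(path, chain_map = default_chain_map(),
                           snapshot_id = NULL, trajectory_id = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  alt <- at$alt
  bad_alt <- !(is.na(alt) | alt %in% c("", " ", "A"))
  if (any(bad_alt)) {
    warning("skipping ", sum(bad_alt), " atoms with alternate location != A")
    at <- at[!bad_alt, , drop = FALSE]
  }
  known <- c(chain_map$protein, chain_map$sgRNA, chain_map$tsDNA)
  if (!all(at$chain %in% known))
    stop("parse error: unknown chain(s): ",
         paste(setdiff(unique(at$chain), known), collapse = ", "))
  if (is.null(snapshot_id))
    snapshot_id <- tools::file_path_sans_ext(basename(path))

  prot <- at[at$chain == chain_map$protein, , drop = FALSE]
  residues <- NULL
  if (nrow(prot)) {
    ca <- prot[prot$elety == "CA", , drop = FALSE]
    missing_ca <- setdiff(unique(prot$resno), ca$resno)
    if (length(missing_ca))
      stop("parse error: protein residue(s) lacking CA atom: ",
           paste(missing_ca, collapse = ", "))
    residues <- data.frame(chain = ca$chain, resno = ca$resno,
                           resname = ca$resid, x = ca$x, y = ca$y, z = ca$z)
    residues <- residues[order(residues$resno), , drop = FALSE]
    rownames(residues) <- NULL
  } else {
    residues <- data.frame(chain = character(), resno = integer(),
                           resname = character(), x = numeric(),
                           y = numeric(), z = numeric())
  }

  nuc_rows <- function(chain, strand) {
    nn <- at[at$chain == chain, , drop = FALSE]
    if (!nrow(nn)) return(NULL)
    c4 <- nn[nn$elety == "C4'", , drop = FALSE]
    missing_c4 <- setdiff(unique(nn$resno), c4$resno)
    if (length(missing_c4))
      stop("parse error: ", strand, " residue(s) lacking C4' atom: ",
           paste(missing_c4, collapse = ", "))
    pos <- c4$resno
    pm <- chain_map$position_map
    if (!is.null(pm)) {
      m <- match(paste(chain, c4$resno), paste(pm$chain, pm$resno))
      if (anyNA(m))
        stop("parse error: no heteroduplex position for ", strand,
             " residue(s): ", paste(c4$resno[is.na(m)], collapse = ", "))
      pos <- pm$position[m]
    }
    data.frame(strand = strand, position = pos, base = c4$resid,
               x = c4$x, y = c4$y, z = c4$z)
  }
  nucleotides <- rbind(nuc_rows(chain_map$sgRNA, "sgRNA"),
                       nuc_rows(chain_map$tsDNA, "tsDNA"))
  if (is.null(nucleotides))
    nucleotides <- data.frame(strand = character(), position = integer(),
                              base = character(), x = numeric(),
                              y = numeric(), z = numeric())
  for (s in unique(nucleotides$strand)) {
    p <- nucleotides$position[nucleotides$strand == s]
    if (anyDuplicated(p))
      stop("parse error: duplicated heteroduplex position(s) on ", s)
  }
  nucleotides <- nucleotides[order(nucleotides$strand, nucleotides$position), ,
                             drop = FALSE]
  rownames(nucleotides) <- NULL
  if (is.null(trajectory_id))
    trajectory_id <- if (nchar(snapshot_id) == 4L)
      parse_snapshot_id(snapshot_id)$trajectory_id else NA_character_
  structure(list(snapshot_id = snapshot_id, trajectory_id = trajectory_id,
                 residues = residues, nucleotides = nucleotides),
            class = "cas9_snapshot")
}

#' Parse a directory of snapshot PDB files
#'
#' @param dir Directory holding `*.pdb` files named by snapshot id.
#' @param chain_map See [default_chain_map()].
#' @return Named list of `cas9_snapshot` grouped by trajectory id.
#' @export
read_snapshot_dir <- function(dir, chain_map = default_chain_map()) {
  paths <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  if (!length(paths)) stop("no PDB files found in ", dir)
  snaps <- lapply(paths, parse_snapshot, chain_map = chain_map)
  split(snaps, vapply(snaps, function(s) s$trajectory_id, ""))
}

#' Parse a four-character structure identifier
#'
#' The first character identifies the starting structure (C for cryo-derived,
#' X for the x-ray structure), the second the mutation (0-9 then A-Z), and
#' the final two digits the snapshot number.
#'
#' @param s A four-character string.
#' @return List with `start_structure`, `mutation_code`, `snapshot_number`,
#'   and the derived `trajectory_id` (first two characters).
#' @export
parse_snapshot_id <- function(s) {
  if (!is.character(s) || length(s) != 1L || nchar(s) != 4L)
    stop("format error: snapshot id must be a single four-character string")
  first <- substr(s, 1, 1)
  if (!first %in% c("C", "X"))
    stop("format error: first character must be C or X, got '", first, "'")
  mut <- substr(s, 2, 2)
  if (!grepl("^[0-9A-Z]$", mut))
    stop("format error: mutation code must be 0-9 or A-Z, got '", mut, "'")
  num <- substr(s, 3, 4)
  if (!grepl("^[0-9]{2}$", num))
    stop("format error: snapshot number must be two digits, got '", num, "'")
  list(start_structure = first, mutation_code = mut,
       snapshot_number = as.integer(num), trajectory_id = substr(s, 1, 2))
}

#' Format a snapshot identifier
#'
#' Inverse of [parse_snapshot_id()].
#'
#' @param start_structure "C" or "X".
#' @param mutation_code One character 0-9 or A-Z.
#' @param snapshot_number Integer 0-99.
#' @return Four-character string.
#' @export
format_snapshot_id <- function(start_structure, mutation_code, snapshot_number) {
  s <- sprintf("%s%s%02d", start_structure, mutation_code,
               as.integer(snapshot_number))
  parse_snapshot_id(s)  # validates
  s
}

flatten_snapshots <- function(snapshots) {
  if (inherits(snapshots, "cas9_snapshot")) return(list(snapshots))
  if (is.list(snapshots) && length(snapshots) &&
      all(vapply(snapshots, inherits, TRUE, "cas9_snapshot")))
    return(snapshots)
  unlist(snapshots, recursive = FALSE)
}

# Squared-distance matrix between two coordinate matrices (n x 3, m x 3).
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

snapshot_coords <- function(snapshot, what = c("residues", "nucleotides")) {
  what <- match.arg(what)
  as.matrix(snapshot[[what]][, c("x", "y", "z")])
}

#' Extract the heteroduplex-proximal residue (HPR) set
#'
#' A residue belongs to the HPR set iff in at least one of the supplied
#' snapshots its Calpha atom lies within `[d_min, d_max]` (inclusive) of the
#' C4' atom of any heteroduplex nucleotide. To avoid leakage the caller must
#' pass training snapshots only (see [make_split()]).
#'
#' @param snapshots List (possibly trajectory-grouped) of `cas9_snapshot`.
#' @param d_min,d_max Distance bounds in Angstrom (default 3 and 7,
#'   inclusive).
#' @return An `hpr_set`: `residues` data.frame (chain, resno) sorted by
#'   residue number, the bounds and the source snapshot ids.
#' @export
compute_hpr_set <- function(snapshots, d_min = 3, d_max = 7) {
  snaps <- flatten_snapshots(snapshots)
  if (!length(snaps)) stop("empty snapshot list")
  hits <- list()
  for (s in snaps) {
    rc <- snapshot_coords(s, "residues")
    nc <- snapshot_coords(s, "nucleotides")
    if (!nrow(rc) || !nrow(nc)) next
    dmin <- apply(cross_dist(rc, nc), 1, min)
    keep <- dmin >= d_min & dmin <= d_max
    if (any(keep))
      hits[[length(hits) + 1L]] <-
        s$residues[keep, c("chain", "resno"), drop = FALSE]
  }
  res <- unique(do.call(rbind, hits))
  if (is.null(res) || !nrow(res))
    res <- data.frame(chain = character(), resno = integer())
  res <- res[order(res$resno), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(residues = res, d_min = d_min, d_max = d_max,
                 source_snapshot_ids = vapply(snaps, function(s)
                   s$snapshot_id, "")),
            class = "hpr_set")
}

#' @export
print.hpr_set <- function(x, ...) {
  cat("HPR set:", nrow(x$residues), "residues within [", x$d_min, ",",
      x$d_max, "] A of a heteroduplex C4' in", length(x$source_snapshot_ids),
      "snapshot(s)\n")
  invisible(x)
}

#' Heteroduplex base-pair C4'-C4' distances
#'
#' Euclidean distance between the sgRNA and tsDNA C4' atoms at each requested
#' heteroduplex position (default the 19 PAM-proximal pairs +1..+19).
#'
#' @param snapshot A `cas9_snapshot`.
#' @param positions Integer vector of positions.
#' @return Named numeric vector of distances in Angstrom.
#' @export
basepair_distances <- function(snapshot, positions = 1:19) {
  nt <- snapshot$nucleotides
  g <- nt[nt$strand == "sgRNA", , drop = FALSE]
  t <- nt[nt$strand == "tsDNA", , drop = FALSE]
  ig <- match(positions, g$position)
  it <- match(positions, t$position)
  if (anyNA(ig) || anyNA(it))
    stop("missing heteroduplex position(s): ",
         paste(positions[is.na(ig) | is.na(it)], collapse = ", "))
  d <- sqrt((g$x[ig] - t$x[it])^2 + (g$y[ig] - t$y[it])^2 +
              (g$z[ig] - t$z[it])^2)
  stats::setNames(d, paste0("+", positions))
}

#' Heteroduplex plasticity sum of a trajectory
#'
#' Sum of the 19 PAM-proximal base-pair C4'-C4' distances over all snapshots
#' of the trajectory.
#'
#' @param snapshots List of `cas9_snapshot` (one trajectory).
#' @param positions Positions included in each per-snapshot sum.
#' @return Non-negative scalar in Angstrom.
#' @export
plasticity_sum <- function(snapshots, positions = 1:19) {
  snaps <- flatten_snapshots(snapshots)
  if (!length(snaps)) stop("empty snapshot list")
  sum(vapply(snaps, function(s) sum(basepair_distances(s, positions)), 0))
}

#' Activity group of a cleavage-activity value
#'
#' Bands: low (< 0.01), medium (0.01-0.1), high (> 0.1); the on-target
#' trajectory forms its own group.
#'
#' @param activity Numeric vector of activities.
#' @param on_target Logical vector (recycled) flagging on-target entries.
#' @return Factor with levels on-target, low, medium, high.
#' @export
activity_group <- function(activity, on_target = FALSE) {
  on_target <- rep_len(on_target, length(activity))
  g <- ifelse(on_target, "on-target",
              ifelse(activity < 0.01, "low",
                     ifelse(activity <= 0.1, "medium", "high")))
  factor(g, levels = c("on-target", "low", "medium", "high"))
}

#' Association between plasticity sums and cleavage activities
#'
#' Spearman (average ranks for ties) and Pearson correlation between
#' per-trajectory plasticity sums and activity labels, plus the activity
#' group of each trajectory.
#'
#' @param sums Numeric vector of per-trajectory plasticity sums.
#' @param activities Numeric vector of activities (same length, >= 3).
#' @param on_target Logical vector flagging the on-target trajectory.
#' @return List with `spearman`, `pearson` (NA with a message when a vector
#'   is constant) and `groups`.
#' @export
plasticity_activity_association <- function(sums, activities,
                                            on_target = FALSE) {
  if (length(sums) != length(activities) || length(sums) < 3)
    stop("sums and activities must have equal length >= 3")
  const <- stats::sd(sums) == 0 || stats::sd(activities) == 0
  if (const) {
    message("correlation undefined: constant input vector")
    sp <- pe <- NA_real_
  } else {
    sp <- stats::cor(sums, activities, method = "spearman")
    pe <- stats::cor(sums, activities, method = "pearson")
  }
  list(spearman = sp, pearson = pe,
       groups = activity_group(activities, on_target))
}

#' Mean pairwise Calpha distance matrix
#'
#' Entry (i, j) is the Euclidean Calpha-Calpha distance between residues i
#' and j averaged over all supplied snapshots.
#'
#' @param snapshots List (possibly grouped) of `cas9_snapshot`.
#' @param residues Integer vector of residue numbers; every residue must be
#'   present in every snapshot.
#' @return Symmetric matrix (Angstrom) with zero diagonal, dimnames the
#'   residue numbers.
#' @export
mean_pairwise_residue_distances <- function(snapshots, residues) {
  snaps <- flatten_snapshots(snapshots)
  if (!length(snaps)) stop("empty snapshot list")
  acc <- matrix(0, length(residues), length(residues))
  for (s in snaps) {
    i <- match(residues, s$residues$resno)
    if (anyNA(i))
      stop("residue(s) absent from snapshot ", s$snapshot_id, ": ",
           paste(residues[is.na(i)], collapse = ", "))
    xyz <- as.matrix(s$residues[i, c("x", "y", "z")])
    acc <- acc + as.matrix(stats::dist(xyz))
  }
  m <- acc / length(snaps)
  dimnames(m) <- list(residues, residues)
  m
}

#' Cluster residues into spatial hotspots
#'
#' Complete-linkage agglomerative clustering of the mean-distance matrix, cut
#' so that no two residues within a cluster exceed `cutoff`. Clusters of size
#' >= 2 are reported as groups ordered by their smallest residue number;
#' singletons form the "other" group.
#'
#' @param mean_distance_matrix Symmetric matrix with zero diagonal (as from
#'   [mean_pairwise_residue_distances()]).
#' @param cutoff Maximum intra-cluster pairwise distance in Angstrom.
#' @return A `residue_clustering`: `clusters` (list of integer vectors),
#'   `singletons`, `cutoff`, `mean_distance_matrix` and `membership` (named
#'   vector mapping residue -> group label, "other" for singletons).
#' @export
cluster_residues <- function(mean_distance_matrix, cutoff = 12) {
  m <- mean_distance_matrix
  if (!is.matrix(m) || nrow(m) != ncol(m) || !isSymmetric(unname(m)))
    stop("mean_distance_matrix must be a symmetric matrix")
  if (any(diag(m) != 0)) stop("mean_distance_matrix must have zero diagonal")
  ids <- as.integer(rownames(m))
  if (nrow(m) == 1L) {
    member <- integer(0)
    cl <- list(); singles <- ids
  } else {
    hc <- stats::hclust(stats::as.dist(m), method = "complete")
    grp <- stats::cutree(hc, h = cutoff)
    parts <- split(ids, grp)
    sizes <- lengths(parts)
    cl <- parts[sizes >= 2]
    cl <- cl[order(vapply(cl, min, 0L))]
    names(cl) <- paste("Group", seq_along(cl))
    singles <- sort(unlist(parts[sizes == 1], use.names = FALSE))
  }
  membership <- stats::setNames(rep("other", length(ids)), ids)
  for (g in names(cl)) membership[as.character(cl[[g]])] <- g
  structure(list(clusters = cl, singletons = singles, cutoff = cutoff,
                 mean_distance_matrix = m, membership = membership),
            class = "residue_clustering")
}

#' @export
print.residue_clustering <- function(x, ...) {
  cat("Residue clustering at", x$cutoff, "A (complete linkage):\n")
  for (g in names(x$clusters))
    cat("  ", g, ": ", paste(x$clusters[[g]], collapse = ", "), "\n", sep = "")
  if (length(x$singletons))
    cat("  other: ", paste(x$singletons, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Residue-base contact count matrix
#'
#' For every (residue, heteroduplex base) combination, counts the snapshots
#' in which the residue's Calpha lies within `[d_min, d_max]` of the base's
#' C4' atom.
#'
#' @param snapshots List (possibly grouped) of `cas9_snapshot`.
#' @param residues Integer vector of residue numbers.
#' @param bases data.frame with columns `strand`, `position`; default all
#'   heteroduplex bases of the first snapshot.
#' @param d_min,d_max Contact bounds in Angstrom.
#' @return Integer matrix residues x bases (base columns named
#'   `<strand>:+<position>`).
#' @export
contact_count_heatmap <- function(snapshots, residues, bases = NULL,
                                  d_min = 3, d_max = 7) {
  snaps <- flatten_snapshots(snapshots)
  if (!length(snaps)) stop("empty snapshot list")
  if (is.null(bases))
    bases <- snaps[[1]]$nucleotides[, c("strand", "position")]
  counts <- matrix(0L, length(residues), nrow(bases),
                   dimnames = list(residues,
                                   paste0(bases$strand, ":+", bases$position)))
  for (s in snaps) {
    ri <- match(residues, s$residues$resno)
    bi <- match(paste(bases$strand, bases$position),
                paste(s$nucleotides$strand, s$nucleotides$position))
    if (anyNA(ri))
      stop("residue(s) absent from snapshot ", s$snapshot_id, ": ",
           paste(residues[is.na(ri)], collapse = ", "))
    if (anyNA(bi))
      stop("base(s) absent from snapshot ", s$snapshot_id)
    d <- cross_dist(snapshot_coords(s, "residues")[ri, , drop = FALSE],
                    snapshot_coords(s, "nucleotides")[bi, , drop = FALSE])
    counts <- counts + (d >= d_min & d <= d_max)
  }
  counts
}
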