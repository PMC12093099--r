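#' Parse a long-format descriptor TSV
#'
#' Canonical header is `snapshot  residue  descriptor  value`; other column
#' names or orders are adapted through `columns`, which maps canonical names
#' to the names present in the file. Duplicate (snapshot, residue,
#' descriptor) keys and non-numeric values are rejected.
#'
#' @param path Path to a tab-separated file.
#' @param columns Named character vector mapping
#'   `c(snapshot=, residue=, descriptor=, value=)` to the file's columns.
#' @return data.frame with the four canonical columns.
#' @export
parse_descriptor_tsv <- function(path,
                                 columns = c(snapshot = "snapshot",
                                             residue = "residue",
                                             descriptor = "descriptor",
                                             value = "value")) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- unname(columns[c("snapshot", "residue", "descriptor", "value")])
  if (!all(need %in% names(raw)))
    stop("missing column(s): ", paste(setdiff(need, names(raw)), collapse = ", "))
  tab <- data.frame(snapshot = raw[[columns[["snapshot"]]]],
                    residue = as.integer(raw[[columns[["residue"]]]]),
                    descriptor = raw[[columns[["descriptor"]]]],
                    value = suppressWarnings(as.numeric(raw[[columns[["value"]]]])))
  bad <- which(is.na(tab$value) & !toupper(raw[[columns[["value"]]]]) %in%
                 c("NA", "NAN", ""))
  if (length(bad))
    stop("non-numeric value at data line ", bad[1], ": '",
         raw[[columns[["value"]]]][bad[1]], "'")
  key <- paste(tab$snapshot, tab$residue, tab$descriptor)
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate record for (snapshot, residue, descriptor) = (",
         gsub(" ", ", ", key[which(dup)[1]]), ")")
  tab
}

#' Write a descriptor table as TSV
#'
#' @param table data.frame with columns snapshot, residue, descriptor, value.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_tsv <- function(table, path) {
  utils::write.table(table[, c("snapshot", "residue", "descriptor", "value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled descriptor-slug classification table
#'
#' Maps descriptor name fragments (regular expressions, matched in order) to
#' the abbreviation and parent descriptor class of the 18 parent classes.
#'
#' @param path Optional path to an alternative table with columns
#'   `pattern`, `abbrev`, `parent_class`.
#' @return data.frame.
#' @export
descriptor_class_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sting_descriptor_classes.tsv",
                        package = "cas9nanoenv")
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}

#' Default SpCas9 domain map
#'
#' Residue-range map from contiguous Cas9 domains to parent domains (REC,
#' RuvC, HNH, PI, bridge helix). Shipped as an editable TSV; the ranges are a
#' conventional SpCas9 annotation and can be replaced wholesale.
#'
#' @param path Optional path to an alternative TSV with columns
#'   `contiguous_domain`, `start`, `end`, `domain`.
#' @return data.frame.
#' @export
default_domain_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "spcas9_domains.tsv",
                        package = "cas9nanoenv")
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}

#' Parse a nanoenvironment feature name into its six properties
#'
#' Feature names follow `Cas9_<residue>_<descriptor slug>[_<GN|SW|WNA|VD>]`.
#' The annotation comprises the Cas9 residue, its domain and contiguous
#' domain (from the domain map), the parent descriptor class and descriptor
#' class (from the slug table), and the neighbour aggregation method.
#' Unknown slugs are annotated as class "unknown" with a warning.
#'
#' @param name Character vector of feature names.
#' @param slug_table See [descriptor_class_table()].
#' @param domain_map See [default_domain_map()].
#' @return data.frame with one row per name: `feature_name`,
#'   `residue_number`, `descriptor`, `aggregation`, `descriptor_class`,
#'   `parent_descriptor_class` (compact form, e.g. "SCO"),
#'   `parent_class_name` (full form), `cas9_domain`, `contiguous_domain`.
#' @export
parse_feature_name <- function(name, slug_table = descriptor_class_table(),
                               domain_map = default_domain_map()) {
  m <- regmatches(name, regexec("^Cas9_([0-9]+)_(.+)$", name))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad))
    stop("malformed feature name: '", name[which(bad)[1]],
         "' (expected Cas9_<residue>_<descriptor slug>[_<agg>])")
  residue <- as.integer(vapply(m, `[`, "", 2))
  slug <- vapply(m, `[`, "", 3)
  agg_m <- regmatches(slug, regexec("^(.*)_(GN|SW|WNA|VD)$", slug))
  has_agg <- vapply(agg_m, length, 0L) == 3L
  aggregation <- ifelse(has_agg, vapply(agg_m, function(x)
    if (length(x) == 3) x[3] else NA_character_, ""), "none")
  core <- ifelse(has_agg, vapply(agg_m, function(x)
    if (length(x) == 3) x[2] else NA_character_, ""), slug)

  parent <- abbrev <- rep(NA_character_, length(name))
  for (i in seq_len(nrow(slug_table))) {
    hit <- is.na(parent) & grepl(slug_table$pattern[i], core)
    parent[hit] <- slug_table$parent_class[i]
    abbrev[hit] <- slug_table$abbrev[i]
  }
  if (anyNA(parent)) {
    warning("unknown descriptor slug(s): ",
            paste(unique(core[is.na(parent)]), collapse = ", "))
    parent[is.na(parent)] <- "unknown"
    abbrev[is.na(abbrev)] <- "unknown"
  }
  # parent class reported in its compact form (SCO, Density, ED, ...)
  dclass <- ifelse(aggregation == "none", abbrev,
                   paste0(abbrev, "-", aggregation))

  dom <- cdom <- rep("unknown", length(name))
  for (i in seq_len(nrow(domain_map))) {
    hit <- residue >= domain_map$start[i] & residue <= domain_map$end[i]
    dom[hit] <- domain_map$domain[i]
    cdom[hit] <- domain_map$contiguous_domain[i]
  }
  data.frame(feature_name = name, residue_number = residue,
             descriptor = slug, aggregation = aggregation,
             descriptor_class = dclass, parent_descriptor_class = abbrev,
             parent_class_name = parent,
             cas9_domain = dom, contiguous_domain = cdom,
             stringsAsFactors = FALSE)
}

#' Parse mismatch metadata labels
#'
#' Decodes base-mutation labels like "T14G" (guide base T replaced by G at
#' heteroduplex position 14) into position, guide base and DNA base, and
#' forms the mismatch interface type as `<guide>:d<DNA>`.
#'
#' @param label Character vector; "ON" (case-insensitive) marks the
#'   on-target interface.
#' @return data.frame with `label`, `on_target`, `position`, `guide_base`,
#'   `dna_base`, `interface_type`.
#' @export
parse_mismatch_label <- function(label) {
  on <- toupper(label) %in% c("ON", "ON-TARGET", "ONTARGET")
  m <- regmatches(label, regexec("^([ACGTU])([0-9]+)([ACGTU])$", label))
  ok <- vapply(m, length, 0L) == 4L
  if (any(!ok & !on))
    stop("malformed mismatch label: '", label[which(!ok & !on)[1]], "'")
  pos <- ifelse(ok, suppressWarnings(as.integer(vapply(m, function(x)
    if (length(x) == 4) x[3] else NA_character_, ""))), NA_integer_)
  g <- ifelse(ok, vapply(m, function(x)
    if (length(x) == 4) x[2] else NA_character_, ""), NA_character_)
  d <- ifelse(ok, vapply(m, function(x)
    if (length(x) == 4) x[4] else NA_character_, ""), NA_character_)
  data.frame(label = label, on_target = on, position = pos, guide_base = g,
             dna_base = d,
             interface_type = ifelse(on, "on-target", paste0(g, ":d", d)),
             stringsAsFactors = FALSE)
}

#' Assemble the labelled nanoenvironment dataset
#'
#' Builds the row-per-snapshot feature matrix whose columns are the (HPR
#' residue x descriptor) pairs present in the descriptor table, named
#' `Cas9_<residue>_<descriptor>`. Columns with any missing value across the
#' snapshots are dropped (and counted); rows are ordered by (trajectory,
#' snapshot number). Every snapshot must map to a labelled trajectory.
#'
#' @param table Descriptor table (see [parse_descriptor_tsv()]).
#' @param hpr An `hpr_set` from [compute_hpr_set()] (computed on training
#'   snapshots only), or an integer vector of residue numbers.
#' @param labels data.frame with columns `trajectory`, `activity`.
#' @param row_metadata Optional data.frame keyed by `trajectory` with extra
#'   per-trajectory columns (e.g. mismatch `label`); merged into `row_info`.
#' @param annotate Logical; annotate columns via [parse_feature_name()].
#' @return A `nanoenv_dataset`: `X` (matrix), `activity` (numeric vector),
#'   `row_info` (trajectory, snapshot_id, ...), `features` (annotation
#'   data.frame or NULL), `dropped_columns` (names).
#' @export
assemble_matrix <- function(table, hpr, labels, row_metadata = NULL,
                            annotate = TRUE) {
  residues <- if (inherits(hpr, "hpr_set")) hpr$residues$resno else
    as.integer(hpr)
  tab <- table[table$residue %in% residues, , drop = FALSE]
  if (!nrow(tab))
    stop("empty intersection between table residues and the HPR set")
  snaps <- sort(unique(tab$snapshot))
  sid <- lapply(snaps, parse_snapshot_id)
  ord <- order(vapply(sid, `[[`, "", "trajectory_id"),
               vapply(sid, `[[`, 0L, "snapshot_number"))
  snaps <- snaps[ord]
  traj <- vapply(sid, `[[`, "", "trajectory_id")[ord]
  lab_i <- match(traj, labels$trajectory)
  if (anyNA(lab_i))
    stop("snapshot(s) without an activity label: trajectory ",
         paste(unique(traj[is.na(lab_i)]), collapse = ", "))

  res_u <- sort(unique(tab$residue))
  desc_u <- sort(unique(tab$descriptor))
  cols <- as.vector(outer(res_u, desc_u, function(r, d) paste0("Cas9_", r, "_", d)))
  X <- matrix(NA_real_, length(snaps), length(cols),
              dimnames = list(snaps, cols))
  ri <- match(tab$snapshot, snaps)
  ci <- match(paste0("Cas9_", tab$residue, "_", tab$descriptor), cols)
  X[cbind(ri, ci)] <- tab$value

  complete <- !apply(is.na(X), 2, any)
  dropped <- cols[!complete]
  if (length(dropped))
    message("dropping ", length(dropped),
            " column(s) with missing values")
  X <- X[, complete, drop = FALSE]

  row_info <- data.frame(trajectory = traj, snapshot_id = snaps,
                         stringsAsFactors = FALSE)
  if (!is.null(row_metadata)) {
    mi <- match(row_info$trajectory, row_metadata$trajectory)
    extra <- row_metadata[mi, setdiff(names(row_metadata), "trajectory"),
                          drop = FALSE]
    row_info <- cbind(row_info, extra)
    rownames(row_info) <- NULL
  }
  features <- if (annotate) parse_feature_name(colnames(X)) else NULL
  structure(list(X = X, activity = labels$activity[lab_i],
                 row_info = row_info, features = features,
                 dropped_columns = dropped),
            class = "nanoenv_dataset")
}

#' @export
print.nanoenv_dataset <- function(x, ...) {
  cat("Nanoenvironment dataset:", nrow(x$X), "snapshots x", ncol(x$X),
      "features (", length(x$dropped_columns), "column(s) dropped ),",
      length(unique(x$row_info$trajectory)), "trajectories\n")
  invisible(x)
}

#' @export
dim.nanoenv_dataset <- function(x) dim(x$X)
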