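# Per-site RMSD series along trajectory frames and mutant-vs-reference
# comparison via Gaussian Kullback-Leibler divergence with mobile/stable
# classification.

#' Read trajectory frames for RMSD analysis
#'
#' Reads PDB files with [bio3d::read.pdb()] and keeps the full atom tables,
#' so arbitrary atom selections remain available (unlike `cas9_snapshot`,
#' which retains Calpha/C4' only).
#'
#' @param paths Character vector of PDB file paths, in frame order.
#' @return List of atom data.frames (chain, resno, resid, elety, x, y, z).
#' @export
read_frames <- function(paths) {
  lapply(paths, function(p) {
    at <- bio3d::read.pdb(p, verbose = FALSE)$atom
    at[at$type %in% c("ATOM", "HETATM"),
       c("chain", "resno", "resid", "elety", "x", "y", "z")]
  })
}

purine_bases <- c("A", "G", "DA", "DG", "RA", "RG")

site_atom_names <- function(atom_selection, resid) {
  if (length(atom_selection) > 1 ||
      !atom_selection %in% c("protein_backbone", "nucleic_anchor",
                             "phosphorus_anchor", "calpha"))
    return(atom_selection)  # custom atom-name vector
  switch(atom_selection,
         protein_backbone = c("N", "CA", "C", "O"),
         calpha = "CA",
         nucleic_anchor = c("P", "O5'", "C5'", "C4'", "C3'", "O3'",
                            if (resid %in% purine_bases) c("C4", "N9")
                            else c("C6", "N1")),
         phosphorus_anchor = c("P", if (resid %in% purine_bases) "N9"
                               else "N1"))
}

frame_site_xyz <- function(frame, site, atom_selection, frame_no) {
  out <- list()
  for (i in seq_along(site$resno)) {
    rows <- frame[frame$chain == site$chain &
                    frame$resno == site$resno[i], , drop = FALSE]
    if (!nrow(rows))
      stop("frame ", frame_no, ": residue ", site$chain, "/",
           site$resno[i], " absent")
    want <- site_atom_names(atom_selection, rows$resid[1])
    have <- rows[rows$elety %in% want, , drop = FALSE]
    miss <- setdiff(want, have$elety)
    if (length(miss))
      stop("frame ", frame_no, ": residue ", site$chain, "/",
           site$resno[i], " missing atom(s) ", paste(miss, collapse = ", "))
    have <- have[order(match(have$elety, want)), , drop = FALSE]
    out[[i]] <- cbind(as.matrix(have[, c("x", "y", "z")]),
                      id = paste(site$resno[i], have$elety))
  }
  ids <- unlist(lapply(out, function(m) m[, 4]))
  xyz <- do.call(rbind, lapply(out, function(m)
    matrix(as.numeric(m[, 1:3]), ncol = 3)))
  rownames(xyz) <- ids
  xyz
}

# Least-squares rigid superposition of frame xyz onto reference using the
# paired fit coordinates (Kabsch via bio3d::fit.xyz).
superpose_frame <- function(ref_fit, mob_fit, mob_all) {
  fixed <- as.vector(t(ref_fit))
  mobile <- as.vector(t(cbind(mob_fit)))
  moved <- bio3d::fit.xyz(fixed = fixed,
                          mobile = as.vector(t(rbind(mob_fit, mob_all))),
                          fixed.inds = seq_along(fixed),
                          mobile.inds = seq_along(mobile))
  matrix(moved, ncol = 3, byrow = TRUE)[-seq_len(nrow(mob_fit)), ,
                                        drop = FALSE]
}

#' Per-site RMSD series along a trajectory
#'
#' RMSD of the selected site atoms in every frame against frame 1. With
#' `superpose = TRUE` each frame is first rigidly superposed onto frame 1 by
#' least squares over all protein Calpha atoms (the fit selection is
#' configurable via `fit_chain`).
#'
#' @param frames List of atom tables from [read_frames()].
#' @param site List with `chain` (single id) and `resno` (integer vector).
#' @param atom_selection One of "protein_backbone" (N, CA, C, O; default),
#'   "nucleic_anchor" (nucleic backbone plus C4/N9 for purines, C6/N1 for
#'   pyrimidines), "phosphorus_anchor" (P plus N9/N1), "calpha", or a custom
#'   character vector of atom names.
#' @param superpose Rigidly superpose each frame onto frame 1 first.
#' @param fit_chain Chain whose CA atoms drive the superposition.
#' @return An `rmsd_series`: `values` (per frame, Angstrom), `mean`, `sd`,
#'   `site`, `atom_selection`.
#' @export
rmsd_series <- function(frames, site, atom_selection = "protein_backbone",
                        superpose = TRUE, fit_chain = "A") {
  if (!length(frames)) stop("no frames")
  ref <- frames[[1]]
  ref_site <- frame_site_xyz(ref, site, atom_selection, 1L)
  ref_fit <- NULL
  if (superpose) {
    ca <- ref[ref$chain == fit_chain & ref$elety == "CA", , drop = FALSE]
    if (!nrow(ca)) stop("no CA atoms on fit chain ", fit_chain)
    fit_ids <- paste(ca$resno)
  }
  values <- vapply(seq_along(frames), function(k) {
    fr <- frames[[k]]
    xyz <- frame_site_xyz(fr, site, atom_selection, k)
    if (!identical(rownames(xyz), rownames(ref_site)))
      stop("frame ", k, ": site atoms do not match frame 1")
    if (superpose) {
      ca_k <- fr[fr$chain == fit_chain & fr$elety == "CA", , drop = FALSE]
      m <- match(fit_ids, paste(ca_k$resno))
      if (anyNA(m))
        stop("frame ", k, ": fit atom CA of residue ",
             fit_ids[which(is.na(m))[1]], " absent")
      ca_ref <- ref[ref$chain == fit_chain & ref$elety == "CA", , drop = FALSE]
      xyz <- superpose_frame(as.matrix(ca_ref[, c("x", "y", "z")]),
                             as.matrix(ca_k[m, c("x", "y", "z")]), xyz)
    }
    sqrt(mean(rowSums((xyz - ref_site)^2)))
  }, 0)
  structure(list(site = site, atom_selection = atom_selection,
                 superposed = superpose, values = values,
                 mean = mean(values), sd = stats::sd(values)),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat("RMSD series (", length(x$values), " frames, ",
      paste(x$atom_selection, collapse = "/"), "): mean ",
      signif(x$mean, 4), " A, sd ", signif(x$sd, 4), " A\n", sep = "")
  invisible(x)
}

#' Gaussian Kullback-Leibler divergence
#'
#' KL(N(mu1, sd1) || N(mu0, sd0)) =
#' ln(sd0/sd1) + (sd1^2 + (mu1 - mu0)^2) / (2 sd0^2) - 1/2.
#'
#' @param mu1,sd1 Parameters of the first (e.g. mutant) normal.
#' @param mu0,sd0 Parameters of the reference normal.
#' @return Non-negative scalar; 0 iff the parameters coincide.
#' @export
gaussian_kl <- function(mu1, sd1, mu0, sd0) {
  if (any(c(sd1, sd0) <= 0)) stop("standard deviations must be positive")
  log(sd0 / sd1) + (sd1^2 + (mu1 - mu0)^2) / (2 * sd0^2) - 0.5
}

#' Classify mutant-site mobility against a reference
#'
#' Computes the Gaussian KL divergence between the mutant and reference RMSD
#' distributions (sample means/sds, n-1 denominator). Sites with divergence
#' below `kl_threshold` are "similar"; otherwise the site is "more_mobile"
#' when the mutant sd exceeds `sd_ratio_threshold` times the reference sd
#' and "more_stable" otherwise.
#'
#' @param mutant,reference `rmsd_series` objects (or numeric RMSD vectors)
#'   of length >= 3.
#' @param kl_threshold Divergence threshold for "similar" (default 0.25).
#' @param sd_ratio_threshold Mutant/reference sd ratio separating mobile
#'   from stable (default 1).
#' @return A `stability_comparison`: `kl`, `delta_mean`, `delta_sd`,
#'   `verdict`.
#' @export
classify_mobility <- function(mutant, reference, kl_threshold = 0.25,
                              sd_ratio_threshold = 1) {
  v1 <- if (inherits(mutant, "rmsd_series")) mutant$values else mutant
  v0 <- if (inherits(reference, "rmsd_series")) reference$values else reference
  if (length(v1) < 3 || length(v0) < 3)
    stop("both series must have length >= 3")
  s1 <- stats::sd(v1); s0 <- stats::sd(v0)
  if (s1 == 0 || s0 == 0)
    stop("degenerate normal: zero sample standard deviation")
  kl <- gaussian_kl(mean(v1), s1, mean(v0), s0)
  verdict <- if (kl < kl_threshold) "similar" else
    if (s1 > sd_ratio_threshold * s0) "more_mobile" else "more_stable"
  structure(list(site = if (inherits(mutant, "rmsd_series")) mutant$site,
                 kl = kl, delta_mean = mean(v1) - mean(v0),
                 delta_sd = s1 - s0, verdict = verdict,
                 kl_threshold = kl_threshold,
                 sd_ratio_threshold = sd_ratio_threshold),
            class = "stability_comparison")
}

#' @export
print.stability_comparison <- function(x, ...) {
  cat(sprintf("KL %.4g | dmean %.3g | dsd %.3g -> %s\n",
              x$kl, x$delta_mean, x$delta_sd, x$verdict))
  invisible(x)
}

#' Per-site stability table for a mutant trajectory
#'
#' Runs [rmsd_series()] for each site on the mutant and reference frame
#' lists and tabulates mean, sd, KL divergence and verdict per site.
#'
#' @param mutant_frames,reference_frames Frame lists from [read_frames()].
#' @param sites List of site lists (`chain`, `resno`), optionally named.
#' @param atom_selection,superpose,fit_chain Passed to [rmsd_series()].
#' @param kl_threshold,sd_ratio_threshold Passed to [classify_mobility()].
#' @return data.frame with one row per site.
#' @export
stability_table <- function(mutant_frames, reference_frames, sites,
                            atom_selection = "protein_backbone",
                            superpose = TRUE, fit_chain = "A",
                            kl_threshold = 0.25, sd_ratio_threshold = 1) {
  rows <- lapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    mut <- rmsd_series(mutant_frames, s, atom_selection, superpose, fit_chain)
    ref <- rmsd_series(reference_frames, s, atom_selection, superpose,
                       fit_chain)
    cmp <- classify_mobility(mut, ref, kl_threshold, sd_ratio_threshold)
    data.frame(site = if (!is.null(names(sites))) names(sites)[i] else
      paste0(s$chain, "/", paste(s$resno, collapse = "+")),
      mutant_mean = mut$mean, mutant_sd = mut$sd,
      reference_mean = ref$mean, reference_sd = ref$sd,
      kl = cmp$kl, verdict = cmp$verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
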