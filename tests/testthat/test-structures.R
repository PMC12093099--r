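test_that("written synthetic PDBs round-trip to identical coordinates", {
  snaps <- generate_snapshots(tiny_config(n_trajectories = 1L,
                                          n_snapshots_per_trajectory = 2L))
  s <- snaps[[1]][[1]]
  path <- withr::local_tempfile(fileext = ".pdb")
  write_snapshot_pdb(s, path)
  back <- parse_snapshot(path, snapshot_id = s$snapshot_id)
  expect_equal(back$residues$resno, s$residues$resno)
  # PDB coordinates carry three decimals: compare to absolute 5e-4
  expect_lt(max(abs(as.matrix(back$residues[, c("x", "y", "z")]) -
                      as.matrix(s$residues[, c("x", "y", "z")]))), 5e-4)
  expect_equal(back$nucleotides$position, s$nucleotides$position)
  expect_equal(back$nucleotides$strand, s$nucleotides$strand)
  expect_lt(max(abs(as.matrix(back$nucleotides[, c("x", "y", "z")]) -
                      as.matrix(s$nucleotides[, c("x", "y", "z")]))), 5e-4)
})

test_that("hand-written PDB fields are extracted literally", {
  txt <- c(
    "ATOM      1  CA  ALA A  10       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A  11       4.000   6.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  SER A  12      -1.500   0.250   9.000  1.00  0.00           C",
    "ATOM      4  C4'   A B   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      5  C4'  DT C   1       6.000   0.000   0.000  1.00  0.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(txt, path)
  s <- parse_snapshot(path, snapshot_id = "C101")
  expect_equal(s$residues$x, c(1, 4, -1.5))
  expect_equal(s$residues$y, c(2, 6, 0.25))
  expect_equal(s$residues$resno, 10:12)
  expect_equal(s$nucleotides$strand, c("sgRNA", "tsDNA"))
  expect_equal(s$nucleotides$x, c(0, 6))
  expect_equal(s$trajectory_id, "C1")
})

test_that("protein residue lacking a CA atom is a named parse error", {
  txt <- c(
    "ATOM      1  CA  ALA A  10       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  GLY A  77       4.000   6.000   3.000  1.00  0.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(txt, path)
  expect_error(parse_snapshot(path, snapshot_id = "C101"), "77")
  txt2 <- c("ATOM      1  CA  ALA Z  10       1.0     2.0     3.0   1.00  0.00           C",
            "END")
  writeLines(txt2, path)
  expect_error(parse_snapshot(path, snapshot_id = "C101"), "unknown chain")
})

test_that("snapshot identifiers decode per the naming scheme and round-trip", {
  id <- parse_snapshot_id("C101")
  expect_equal(id$start_structure, "C")
  expect_equal(id$mutation_code, "1")
  expect_equal(id$snapshot_number, 1L)
  id2 <- parse_snapshot_id("XA23")
  expect_equal(id2$start_structure, "X")
  expect_equal(id2$mutation_code, "A")
  expect_equal(id2$snapshot_number, 23L)
  expect_equal(format_snapshot_id("X", "A", 23), "XA23")
  expect_error(parse_snapshot_id("5F9R"), "C or X")
  expect_error(parse_snapshot_id("C1"), "four-character")
  expect_error(parse_snapshot_id("C1xy"), "two digits")
})

make_snapshot <- function(res_xyz, nuc_xyz, id = "C101") {
  structure(list(
    snapshot_id = id, trajectory_id = substr(id, 1, 2),
    residues = data.frame(chain = "A", resno = seq_len(nrow(res_xyz)),
                          resname = "ALA", x = res_xyz[, 1], y = res_xyz[, 2],
                          z = res_xyz[, 3]),
    nucleotides = data.frame(strand = rep(c("sgRNA", "tsDNA"),
                                          each = nrow(nuc_xyz) / 2),
                             position = rep(seq_len(nrow(nuc_xyz) / 2), 2),
                             base = "A", x = nuc_xyz[, 1], y = nuc_xyz[, 2],
                             z = nuc_xyz[, 3])),
    class = "cas9_snapshot")
}

test_that("HPR membership follows the inclusive 3-7 A rule", {
  nuc <- rbind(c(0, 0, 0), c(6, 0, 0))  # one base pair, strands 6 A apart
  res <- rbind(c(-2.5, 0, 0), c(-5, 0, 0), c(-8, 0, 0), c(-3, 0, 0),
               c(-7, 0, 0))  # nearest-C4' distances 2.5, 5, 8, 3, 7
  s <- make_snapshot(res, nuc)
  h <- compute_hpr_set(list(s))
  expect_equal(h$residues$resno, c(2L, 4L, 5L))  # 5.0, and both boundaries
  expect_error(compute_hpr_set(list()), "empty")
})

test_that("HPR extraction agrees with the brute-force double loop and is monotone", {
  for (seed in 1:3) {
    cfg <- tiny_config(seed = seed, jitter_sd = 1.5)
    snaps <- generate_snapshots(cfg)
    flat <- unlist(snaps, recursive = FALSE)
    expect_identical(compute_hpr_set(flat)$residues$resno,
                     brute_force_hpr(flat))
    sub <- compute_hpr_set(flat[1:5])$residues$resno
    full <- compute_hpr_set(flat)$residues$resno
    expect_true(all(sub %in% full))
  }
})

test_that("base-pair distances match hand geometry and are translation invariant", {
  nuc <- rbind(c(0, 0, 0), c(1, 1, 1), c(3, 4, 0), c(1, 1, 1))
  s <- make_snapshot(rbind(c(50, 50, 50)), nuc)
  d <- basepair_distances(s, positions = 1:2)
  expect_equal(unname(d), c(5, 0))  # 3-4-5 triangle; coincident atoms
  set.seed(1)
  s2 <- rigid_snapshot(s, diag(3), c(10, -4, 2))
  expect_equal(basepair_distances(s2, 1:2), d)
  expect_error(basepair_distances(s, positions = 1:3), "3")
})

test_that("plasticity sum accumulates base-pair distances over snapshots", {
  cfg <- tiny_config(jitter_sd = 0)
  tr <- generate_snapshots(cfg)[[1]]
  one <- sum(basepair_distances(tr[[1]]))
  expect_equal(plasticity_sum(tr[1]), one)
  expect_equal(plasticity_sum(tr), length(tr) * one)
  # constructed: every pair distance 5 A over 2 snapshots -> 2 * 19 * 5
  nuc <- cbind(0, rep(c(0, 5), each = 20), rep(5 * (0:19), 2))
  nuc[21:40, 2] <- 3; nuc[21:40, 1] <- 4  # tsDNA offset by (4,3): distance 5
  nuc[1:20, 1] <- 0; nuc[1:20, 2] <- 0
  s <- make_snapshot(rbind(c(100, 100, 100)), nuc)
  expect_equal(plasticity_sum(list(s, s)), 2 * 19 * 5)
})

test_that("plasticity-activity association matches the rank-formula oracle", {
  a <- c(0.005, 0.2, 0.04, 0.8, 0.11)
  s <- c(100, 180, 120, 150, 170)
  res <- plasticity_activity_association(s, a)
  expect_equal(res$spearman, spearman_formula(s, a))
  expect_equal(res$pearson, pearson_formula(s, a))
  expect_equal(as.character(res$groups),
               c("low", "high", "medium", "high", "high"))
  ident <- plasticity_activity_association(a, a)
  expect_equal(ident$spearman, 1)
  expect_equal(ident$pearson, 1)
  rev <- plasticity_activity_association(rev(sort(a)), sort(a))
  expect_equal(rev$spearman, -1)
  expect_message(
    out <- plasticity_activity_association(c(1, 1, 1), a[1:3]), "constant")
  expect_true(is.na(out$spearman))
})

test_that("mean pairwise distances average per-snapshot metrics", {
  r1 <- rbind(c(0, 0, 0), c(4, 0, 0))
  r2 <- rbind(c(0, 0, 0), c(6, 0, 0))
  nuc <- rbind(c(50, 0, 0), c(50, 6, 0))
  s1 <- make_snapshot(r1, nuc); s2 <- make_snapshot(r2, nuc, "C102")
  m <- mean_pairwise_residue_distances(list(s1, s2), 1:2)
  expect_equal(m["1", "2"], 5)
  expect_true(isSymmetric(unname(m)))
  expect_equal(diag(m), c("1" = 0, "2" = 0))
  expect_error(mean_pairwise_residue_distances(list(s1), c(1, 3)), "3")
})

test_that("complete-linkage clustering honours the 12 A ceiling", {
  m <- matrix(c(0, 10, 13, 10, 0, 10, 13, 10, 0), 3,
              dimnames = list(c(101, 102, 103), c(101, 102, 103)))
  cl <- cluster_residues(m, cutoff = 12)
  expect_equal(cl$clusters, list("Group 1" = c(101L, 102L)))
  expect_equal(cl$singletons, 103L)
  expect_equal(unname(cl$membership), c("Group 1", "Group 1", "other"))
  two <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c(7, 9), c(7, 9)))
  expect_equal(cluster_residues(two, 12)$clusters[["Group 1"]], c(7L, 9L))
  expect_error(cluster_residues(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("clustering invariant holds on random geometries", {
  set.seed(11)
  for (rep in 1:5) {
    pts <- matrix(runif(3 * 12, 0, 40), ncol = 3)
    m <- as.matrix(dist(pts))
    dimnames(m) <- list(1:12, 1:12)
    cl <- cluster_residues(m, cutoff = 12)
    for (g in cl$clusters) {
      sub <- m[as.character(g), as.character(g)]
      expect_lte(max(sub), 12)
    }
    part <- sort(c(unlist(cl$clusters, use.names = FALSE), cl$singletons))
    expect_equal(part, 1:12)
  }
})

test_that("contact counts respect the snapshot-count bound and the shell", {
  nuc <- rbind(c(0, 0, 0), c(6, 0, 0))
  near <- make_snapshot(rbind(c(-5, 0, 0), c(-30, 0, 0)), nuc)
  snaps <- rep(list(near), 10)
  cc <- contact_count_heatmap(snaps, residues = 1:2)
  expect_equal(unname(cc[1, ]), c(10, 0))  # 5 A and 11 A from the two bases
  expect_equal(unname(cc[2, ]), c(0, 0))
  expect_true(all(cc <= length(snaps)))
})

test_that("geometric operations are invariant under rigid translation", {
  cfg <- tiny_config(n_trajectories = 1L, n_snapshots_per_trajectory = 3L)
  tr <- generate_snapshots(cfg)[[1]]
  shift <- c(12.3, -45.6, 7.8)
  tr2 <- lapply(tr, rigid_snapshot, R = diag(3), t = shift)
  expect_equal(compute_hpr_set(tr2)$residues, compute_hpr_set(tr)$residues)
  expect_equal(plasticity_sum(tr2), plasticity_sum(tr))
  expect_equal(mean_pairwise_residue_distances(tr2, 1:5),
               mean_pairwise_residue_distances(tr, 1:5))
  expect_equal(contact_count_heatmap(tr2, 1:5),
               contact_count_heatmap(tr, 1:5))
})
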