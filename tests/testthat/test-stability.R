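frame_df <- function(xyz, chain = "A", resno = NULL, elety = "CA",
                     resid = "ALA") {
  if (is.null(resno)) resno <- seq_len(nrow(xyz))
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

test_that("identical frames give an all-zero RMSD series", {
  xyz <- matrix(rnorm(30), 10, 3)
  f <- frame_df(xyz)
  s <- rmsd_series(list(f, f, f), site = list(chain = "A", resno = 3:5),
                   atom_selection = "calpha")
  expect_equal(s$values, c(0, 0, 0))
  expect_true(all(s$values >= 0))
})

test_that("rigid translation is absorbed by superposition and measured without it", {
  set.seed(8)
  xyz <- matrix(rnorm(30, sd = 5), 10, 3)
  f1 <- frame_df(xyz)
  f2 <- frame_df(sweep(xyz, 2, c(1, 0, 0), "+"))
  no_fit <- rmsd_series(list(f1, f2), list(chain = "A", resno = 1:10),
                        atom_selection = "calpha", superpose = FALSE)
  expect_equal(no_fit$values[2], 1)
  fit <- rmsd_series(list(f1, f2), list(chain = "A", resno = 1:10),
                     atom_selection = "calpha", superpose = TRUE)
  expect_equal(fit$values[2], 0, tolerance = 1e-6)
})

test_that("superposed RMSD is invariant under arbitrary rigid motions per frame", {
  set.seed(9)
  base <- matrix(rnorm(36, sd = 4), 12, 3)
  frames <- lapply(1:4, function(k)
    frame_df(base + matrix(rnorm(36, sd = 0.3), 12, 3)))
  ref <- rmsd_series(frames, list(chain = "A", resno = c(2, 5, 9)),
                     atom_selection = "calpha", superpose = TRUE)
  moved <- lapply(frames, function(f) {
    R <- random_rotation(); t <- rnorm(3, sd = 20)
    xyz <- as.matrix(f[, c("x", "y", "z")]) %*% t(R)
    f$x <- xyz[, 1] + t[1]; f$y <- xyz[, 2] + t[2]; f$z <- xyz[, 3] + t[3]
    f
  })
  got <- rmsd_series(moved, list(chain = "A", resno = c(2, 5, 9)),
                     atom_selection = "calpha", superpose = TRUE)
  expect_equal(got$values, ref$values, tolerance = 1e-6)
})

test_that("missing site atoms are reported with frame and atom", {
  f1 <- frame_df(matrix(rnorm(9), 3, 3))
  f2 <- f1[-2, ]
  expect_error(rmsd_series(list(f1, f2), list(chain = "A", resno = 1:3),
                           atom_selection = "calpha", superpose = FALSE),
               "frame 2.*2")
  f3 <- frame_df(matrix(rnorm(9), 3, 3))
  expect_error(rmsd_series(list(f3), list(chain = "A", resno = 1),
                           atom_selection = "protein_backbone",
                           superpose = FALSE),
               "missing atom")
})

test_that("nucleic anchor selections depend on purine/pyrimidine identity", {
  expect_setequal(cas9nanoenv:::site_atom_names("phosphorus_anchor", "DA"),
                  c("P", "N9"))
  expect_setequal(cas9nanoenv:::site_atom_names("phosphorus_anchor", "DT"),
                  c("P", "N1"))
  expect_true("N9" %in% cas9nanoenv:::site_atom_names("nucleic_anchor", "G"))
  expect_true("C6" %in% cas9nanoenv:::site_atom_names("nucleic_anchor", "U"))
})

test_that("Gaussian KL matches its closed form and numerical integration", {
  expect_equal(gaussian_kl(0, 1, 0, 1), 0)
  expect_equal(gaussian_kl(1, 1, 0, 1), 0.5)
  expect_equal(gaussian_kl(0, 2, 0, 1), log(1 / 2) + 4 / 2 - 1 / 2)
  # asymmetry
  expect_false(isTRUE(all.equal(gaussian_kl(0, 2, 0, 1),
                                gaussian_kl(0, 1, 0, 2))))
  expect_error(gaussian_kl(0, 0, 0, 1), "positive")
  set.seed(10)
  for (rep in 1:12) {
    mu1 <- runif(1, -5, 5); mu0 <- runif(1, -5, 5)
    sd1 <- runif(1, 0.1, 5); sd0 <- runif(1, 0.1, 5)
    expect_equal(gaussian_kl(mu1, sd1, mu0, sd0),
                 numeric_kl(mu1, sd1, mu0, sd0), tolerance = 1e-6)
  }
})

test_that("mobility classification separates mobile from stable sites", {
  set.seed(12)
  ref <- rnorm(50, 2, 0.5)
  same <- classify_mobility(ref, ref)
  expect_equal(same$verdict, "similar")
  expect_equal(same$kl, 0)
  mobile <- classify_mobility(ref * 2 - mean(ref) * 1, ref)
  # doubled sd, roughly equal mean: KL > 0.25 for any sd ratio of 2
  expect_equal(mobile$verdict, "more_mobile")
  stable <- classify_mobility(mean(ref) + (ref - mean(ref)) / 2, ref)
  expect_equal(stable$verdict, "more_stable")
  expect_error(classify_mobility(c(1, 1, 1), ref), "zero sample")
  expect_error(classify_mobility(ref[1:2], ref), "length")
})

test_that("mobility verdicts are antisymmetric in the sd comparison", {
  set.seed(13)
  for (rep in 1:5) {
    a <- rnorm(30, 1, runif(1, 0.2, 1))
    b <- rnorm(30, 1, runif(1, 1.5, 3))
    ab <- classify_mobility(a, b, kl_threshold = 0)
    ba <- classify_mobility(b, a, kl_threshold = 0)
    expect_true(ab$verdict != ba$verdict)
    expect_setequal(c(ab$verdict, ba$verdict),
                    c("more_mobile", "more_stable"))
  }
})

test_that("stability tables compare every site of a mutant against the reference", {
  cfg <- tiny_config(n_trajectories = 2L, n_snapshots_per_trajectory = 6L,
                     jitter_sd = 0.4)
  snaps <- generate_snapshots(cfg)
  to_frames <- function(tr) lapply(tr, cas9nanoenv:::snapshot_frame)
  tab <- stability_table(to_frames(snaps[[2]]), to_frames(snaps[[1]]),
                         sites = list(list(chain = "A", resno = 1L),
                                      list(chain = "A", resno = 5L)),
                         atom_selection = "calpha")
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$kl >= 0))
  expect_true(all(tab$verdict %in% c("similar", "more_mobile",
                                     "more_stable")))
})

test_that("PDB-backed frames feed the RMSD machinery", {
  cfg <- tiny_config(n_trajectories = 1L, n_snapshots_per_trajectory = 3L,
                     jitter_sd = 0.5)
  dir <- withr::local_tempdir()
  write_snapshots(generate_snapshots(cfg), dir)
  frames <- read_frames(sort(list.files(dir, full.names = TRUE)))
  s <- rmsd_series(frames, list(chain = "A", resno = 1:3),
                   atom_selection = "calpha")
  expect_equal(s$values[1], 0)
  expect_length(s$values, 3L)
  expect_true(all(s$values >= 0))
})
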