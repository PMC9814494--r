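# The seeded generators: bit-reproducibility, exact ground truth, and the
# closed loop with the analysis operations.

test_that("conformer building is deterministic and closes the helicity loop", {
  seqA <- synthetic_pkid_sequence()
  s1 <- build_conformer(seqA, rep(FALSE, 29L), seed = 5)
  s2 <- build_conformer(seqA, rep(FALSE, 29L), seed = 5)
  expect_identical(s1$xyz, s2$xyz)
  s3 <- build_conformer(seqA, rep(FALSE, 29L), seed = 6)
  expect_false(identical(s1$xyz, s3$xyz))
  # all-helix vector: every interior residue helical
  sh <- build_conformer(seqA, rep(TRUE, 29L), resno_start = 119L)
  h <- assign_helix(sh)
  expect_true(all(h[as.character(120:146)]))
  # all-coil: zero helicity
  expect_false(any(assign_helix(s1)))
  expect_error(build_conformer(c("ALA", "XXX"), c(FALSE, FALSE)), "XXX")
})

test_that("free ensembles carry exact helix and HRC ground truth", {
  seqA <- synthetic_pkid_sequence()
  prof <- c(0, rep(0.5, 10L), rep(0, 4L), rep(0.15, 11L), rep(0, 3L))
  g <- generate_free_ensemble(seqA, prof, n_frames = 120L, seed = 19,
                              p_hrc = 0.4)
  # helicity equals the per-frame truth exactly (all-or-none runs)
  prof_hat <- helicity(g$ensemble)
  expect_equal(prof_hat$helicity, unname(colMeans(g$truth$helix)))
  # HRC probability equals the flag fraction exactly
  expect_equal(hrc_probability(g$ensemble, hrc_spec(chain = "A")),
               mean(g$truth$hrc))
  # p_hrc = 0 and 1 are exact
  g0 <- generate_free_ensemble(seqA, prof, n_frames = 40L, seed = 20, p_hrc = 0)
  expect_equal(hrc_probability(g0$ensemble, hrc_spec(chain = "A")), 0)
  g1 <- generate_free_ensemble(seqA, prof, n_frames = 40L, seed = 21, p_hrc = 1)
  expect_equal(hrc_probability(g1$ensemble, hrc_spec(chain = "A")), 1)
  # same seed: bit-identical ensembles
  g0b <- generate_free_ensemble(seqA, prof, n_frames = 40L, seed = 20, p_hrc = 0)
  expect_identical(g0$ensemble$xyz, g0b$ensemble$xyz)
  # short positive runs are flagged as undetectable
  expect_warning(generate_free_ensemble(seqA[1:6], c(0, 0.5, 0.5, 0, 0, 0),
                                        n_frames = 2L, seed = 1),
                 "shorter than min_run")
})

test_that("generated structures satisfy the container invariants and round-trip", {
  seqA <- synthetic_pkid_sequence()
  g <- generate_free_ensemble(seqA, rep(0, 29L), n_frames = 3L, seed = 22,
                              p_hrc = 0.5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(g$ensemble, f)
  e2 <- read_pdb_ensemble(f)
  expect_equal(e2$atoms$elety, g$ensemble$atoms$elety)
  expect_lt(max(abs(e2$xyz - g$ensemble$xyz)), 5.1e-4)
  # HRC classification survives the 3-decimal coordinate rounding
  expect_equal(hrc_counts(e2, hrc_spec(chain = "A")),
               hrc_counts(g$ensemble, hrc_spec(chain = "A")))
})

test_that("the reference complex realises exactly the designed interface", {
  ref <- demo_reference()
  iface <- demo_interface()
  ncs <- native_contacts_from_reference(ref, "A", "B")
  expect_setequal(paste(ncs$res_a, ncs$res_b),
                  paste0("A:", iface$idp, " B:", iface$partner))
  expect_equal(q_fraction(ref, ncs)$q, 1)
  expect_identical(ref$xyz, demo_reference()$xyz)  # deterministic
})

test_that("complex ensembles recover distances, Q and mixture fractions", {
  ref <- demo_reference()
  ncs <- native_contacts_from_reference(ref, "A", "B")
  # single far state with Q = 0: d_com recovered to the draw, Q exactly 0
  mixF <- state_mixture("F", 1, d_mean = 40, d_sd = 2, q_mean = 0, q_sd = 0)
  gF <- generate_complex_ensemble(ref, mixF, n_frames = 60L, seed = 29)
  cvF <- cv_table(gF$ensemble, ncs)
  expect_true(all(cvF$q == 0))
  expect_lt(max(abs(cvF$d_com - gF$truth$d_target)), 1)
  # two-state mixture: n_native matches the per-frame target exactly and
  # empirical fractions sit within 3 binomial SE
  mix <- state_mixture(c("F", "B"), c(0.5, 0.5), d_mean = c(40, 19),
                       d_sd = c(2, 0.5), q_mean = c(0, 0.85),
                       q_sd = c(0, 0.05))
  n <- 400L
  g2 <- generate_complex_ensemble(ref, mix, n_frames = n, seed = 31)
  cv2 <- cv_table(g2$ensemble, ncs)
  expect_true(all(cv2$n_native == g2$truth$n_target))
  fr <- mean(g2$truth$state == "B")
  expect_lt(abs(fr - 0.5), 3 * sqrt(0.25 / n))
  # determinism
  g2b <- generate_complex_ensemble(ref, mix, n_frames = n, seed = 31)
  expect_identical(g2$ensemble$xyz, g2b$ensemble$xyz)
})

test_that("impossible mixtures are rejected at validation", {
  ref <- demo_reference()
  expect_error(state_mixture(c("A", "B"), c(0.6, 0.6), c(40, 19), c(1, 1),
                             c(0, 0.5), c(0, 0)), "sum to 1")
  # full native contacts at 60 A separation cannot be realised
  mix_bad <- state_mixture("X", 1, d_mean = 60, d_sd = 0, q_mean = 1, q_sd = 0)
  expect_error(generate_complex_ensemble(ref, mix_bad, n_frames = 5L, seed = 1),
               "unreachable")
})

test_that("cluster-table generation is seeded and honours the O rules", {
  c1 <- generate_cluster_table(30L, o_rule = "random", seed = 7)
  c2 <- generate_cluster_table(30L, o_rule = "random", seed = 7)
  expect_identical(c1, c2)
  cl <- generate_cluster_table(10L, o_rule = "linear", o_value = 2, seed = 8)
  expect_equal(cl$o_alpha, 2 * cl$f_alpha)
  expect_equal(nrow(generate_cluster_table(1L, seed = 9)), 1L)
})
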