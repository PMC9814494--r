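# Dihedral-based helicity, expanding-window errors, helix axes, and
# chemical-shift comparison.

seq10 <- setNames(rep("ALA", 10L), 1:10)

test_that("backbone dihedrals agree with bio3d on a built conformer", {
  s <- build_conformer(synthetic_pkid_sequence(), rep(TRUE, 29L),
                       resno_start = 119L)
  d <- backbone_dihedrals(s)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(s, f)
  ref <- bio3d::torsion.pdb(bio3d::read.pdb(f, verbose = FALSE))
  expect_equal(d$phi[-1L], unname(ref$phi[-1L]), tolerance = 1e-3)
  expect_equal(d$psi[-29L], unname(ref$psi[-29L]), tolerance = 1e-3)
})

test_that("the dihedral-window + run rule assigns helices as constructed", {
  # ideal helix: all interior residues helical, termini never
  s <- build_conformer(seq10, rep(TRUE, 10L))
  h <- assign_helix(s)
  expect_false(h[["1"]]); expect_false(h[["10"]])
  expect_true(all(h[as.character(2:9)]))
  # extended chain: nothing helical
  ext <- build_conformer(seq10, matrix(rep(c(-120, 120), each = 10L), 10L))
  expect_false(any(assign_helix(ext)))
  # a 3-residue alpha-window run embedded in coil stays non-helical
  st <- rep(FALSE, 10L); st[4:6] <- TRUE
  s3 <- build_conformer(seq10, st, seed = 9)
  expect_false(any(assign_helix(s3)))
  # ... but a 4-residue run is detected
  st[7L] <- TRUE
  s4 <- build_conformer(seq10, st, seed = 9)
  expect_equal(names(which(assign_helix(s4))), as.character(4:7))
  # assignment is rigid-motion invariant (internal coordinates)
  set.seed(13)
  expect_identical(assign_helix(random_rigid_motion(s4)), assign_helix(s4))
})

test_that("missing backbone atoms are reported by residue", {
  s <- build_conformer(seq10, rep(TRUE, 10L))
  keep <- !(s$atoms$resno == 5L & s$atoms$elety == "CA")
  s$atoms <- s$atoms[keep, ]; s$xyz <- s$xyz[keep, , drop = FALSE]
  expect_error(assign_helix(s), "CA in residue A:5")
})

test_that("ensemble helicity is the weighted fraction of helical frames", {
  helix <- build_conformer(seq10, rep(TRUE, 10L))
  ext <- build_conformer(seq10, matrix(rep(c(-120, 120), each = 10L), 10L))
  e <- idp_ensemble(helix$atoms, list(helix$xyz, ext$xyz))
  prof <- helicity(e)
  expect_equal(prof$helicity[2:9], rep(0.5, 8L))
  expect_equal(prof$helicity[c(1L, 10L)], c(0, 0))
  e0 <- idp_ensemble(ext$atoms, list(ext$xyz, ext$xyz))
  expect_true(all(helicity(e0)$helicity == 0))
  # region summaries
  expect_equal(region_helicity(prof, c(2L, 9L)), 0.5)
  expect_equal(region_helicity(data.frame(resno = 1:2, helicity = c(1, 0)),
                               c(1L, 2L)), 0.5)
  expect_equal(region_helicity(prof, c(3L, 3L)), prof$helicity[3L])
  expect_error(region_helicity(prof, c(8L, 12L)), "region")
})

test_that("expanding-window errors use last-third endpoints and vanish for stationary input", {
  helix <- build_conformer(seq10, rep(TRUE, 10L))
  e <- idp_ensemble(helix$atoms, rep(list(helix$xyz), 300L))
  prof <- expanding_window_error(e, n_windows = 5L)
  expect_equal(attr(prof, "window_ends"), c(220, 240, 260, 280, 300))
  expect_lt(max(prof$std), 1e-12)
  # non-stationary input: std > 0 somewhere, and invariant to weight scale
  ext <- build_conformer(seq10, matrix(rep(c(-120, 120), each = 10L), 10L))
  frames <- c(rep(list(helix$xyz), 150L), rep(list(ext$xyz), 150L))
  e2 <- idp_ensemble(helix$atoms, frames)
  p2 <- expanding_window_error(e2, n_windows = 5L)
  expect_gt(max(p2$std), 0)
  p3 <- expanding_window_error(set_weights(e2, rep(2, 300L)), n_windows = 5L)
  expect_equal(p3$std, p2$std)
  expect_error(expanding_window_error(subset_frames(e, 1:3), n_windows = 5L),
               "too few frames")
})

test_that("helix axes are oriented N-to-C and give the constructed angles", {
  s <- build_conformer(setNames(rep("ALA", 12L), 1:12), rep(TRUE, 12L))
  ax <- helix_axis(s, c(1L, 12L))
  expect_equal(sqrt(sum(ax^2)), 1)
  # ideal helix axis: compare against the CA displacement direction
  ca <- s$xyz[select_atoms(s, "alpha-carbon"), ]
  disp <- ca[12L, ] - ca[1L, ]
  ang <- acos(sum(ax * disp / sqrt(sum(disp^2)))) * 180 / pi
  expect_lt(ang, 5)
  # rotating the structure to put the axis on z gives (0,0,1) within 5 deg
  sz <- s; sz$xyz <- s$xyz %*% idpfel:::.rotation_between(ax, c(0, 0, 1)) |> unname()
  sz$xyz <- s$xyz %*% t(idpfel:::.rotation_between(ax, c(0, 0, 1)))
  az <- helix_axis(sz, c(1L, 12L))
  expect_lt(acos(min(1, sum(az * c(0, 0, 1)))) * 180 / pi, 5)
  # same region -> 0 degrees
  expect_equal(interhelix_angle(s, c(1L, 12L), c(1L, 12L)), 0)
  # two copies rotated by 90 and 180 degrees about x, starting from a
  # z-aligned helix so the rotation angle is the inter-axis angle
  sz2 <- s; sz2$xyz <- s$xyz %*% t(idpfel:::.rotation_between(ax, c(0, 0, 1)))
  two_chain_angle <- function(theta) {
    th <- theta * pi / 180
    Rx <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3L)
    b <- sz2; b$atoms$chain <- "B"; b$xyz <- sz2$xyz %*% t(Rx)
    b$xyz[, 1L] <- b$xyz[, 1L] + 100
    cplx <- idp_structure(rbind(sz2$atoms, b$atoms), rbind(sz2$xyz, b$xyz))
    acos(max(-1, min(1, sum(helix_axis(cplx, c(1L, 12L), chain = "A") *
               helix_axis(cplx, c(1L, 12L), chain = "B"))))) * 180 / pi
  }
  expect_equal(two_chain_angle(90), 90, tolerance = 2e-2)
  expect_equal(two_chain_angle(180), 180, tolerance = 2e-2)
  expect_error(helix_axis(s, c(1L, 3L)), ">= 4")
})

test_that("shift RMSE compares common residues only", {
  pred <- data.frame(residue = 1:5, nucleus = "CA",
                     shift = c(58.1, 57.9, 56.4, 58.8, 57.0))
  expect_equal(shift_rmse(pred, pred, "CA")$rmse, 0)
  off <- pred; off$shift <- off$shift + 1
  r <- shift_rmse(pred, off, "CA")
  expect_equal(r$rmse, 1)
  expect_equal(r$n_residues, 5L)
  # hand-computed on partially overlapping tables
  exp_tab <- data.frame(residue = 3:7, nucleus = "CA",
                        shift = c(56.0, 59.0, 57.5, 58.0, 55.0))
  r2 <- shift_rmse(pred, exp_tab, "CA")
  hand <- sqrt(mean(c(56.4 - 56.0, 58.8 - 59.0, 57.0 - 57.5)^2))
  expect_equal(r2$rmse, hand, tolerance = 1e-12)
  expect_equal(r2$n_residues, 3L)
  expect_error(shift_rmse(pred, data.frame(residue = 9L, nucleus = "CA",
                                           shift = 1), "CA"), "no common")
  expect_error(shift_rmse(pred, exp_tab, "HA"), "no common")
})
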