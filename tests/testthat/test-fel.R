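# Weighted free-energy landscapes, basin detection, state assignment,
# indicator projection, and Boltzmann reweighting.

kB <- 0.008314462618

cv_from_points <- function(x, y, w = NULL) {
  df <- data.frame(d_com = x, n_native = y)
  if (!is.null(w)) df$weight <- w
  df
}

ax <- function(name, min, max, width) fel_axis(name, min, max, width)

test_that("binned free energies follow -kT log P with a zero minimum", {
  # all frames in one bin
  cv <- cv_from_points(c(1.1, 1.2, 1.3), c(0.5, 0.5, 0.5))
  fel <- weighted_fel(cv, ax("d_com", 0, 2, 1), ax("n_native", 0, 2, 1))
  expect_equal(fel$f[2L, 1L], 0)
  expect_true(all(is.infinite(fel$f[-2L])))
  # two bins with weights 2w : w differ by kT log 2
  cv2 <- cv_from_points(c(0.5, 1.5), c(0.5, 0.5), w = c(2, 1))
  fel2 <- weighted_fel(cv2, ax("d_com", 0, 2, 1), ax("n_native", 0, 2, 1),
                       temperature = 300)
  expect_equal(fel2$f[2L, 1L] - fel2$f[1L, 1L], kB * 300 * log(2),
               tolerance = 1e-12)
  expect_equal(kB * 300 * log(2), 1.7288, tolerance = 1e-4)
  # round-trip: renormalised exp(-F/kT) equals the binned distribution
  p_back <- exp(-fel2$f / (kB * 300))
  p_back <- p_back / sum(p_back)
  expect_equal(p_back, fel2$p, tolerance = 1e-12)
  # weight-scale invariance
  fel2b <- weighted_fel(cv_from_points(c(0.5, 1.5), c(0.5, 0.5), w = c(20, 10)),
                        ax("d_com", 0, 2, 1), ax("n_native", 0, 2, 1))
  expect_equal(fel2b$f, fel2$f)
  expect_error(weighted_fel(cv_from_points(9, 9), ax("d_com", 0, 2, 1),
                            ax("n_native", 0, 2, 1)), "inside the axes")
  expect_error(fel_axis("x", 0, 2, -1), "width")
})

test_that("a 2D Gaussian sample recovers the analytic quadratic surface", {
  set.seed(91)
  n <- 1e5
  x <- rnorm(n, 0, 1); y <- rnorm(n, 0, 1)
  fel <- weighted_fel(cv_from_points(x, y), ax("d_com", -3, 3, 0.25),
                      ax("n_native", -3, 3, 0.25), temperature = 300)
  counts <- fel$p * n
  cx <- idpfel:::.axis_centers(fel$axis1)
  cy <- idpfel:::.axis_centers(fel$axis2)
  analytic <- outer(cx, cy, function(a, b) kB * 300 * (a^2 + b^2) / 2)
  analytic <- analytic - min(analytic[counts >= 100])
  dev <- abs(fel$f - analytic)[counts >= 100]
  expect_lt(max(dev), 0.5)
})

test_that("basin detection finds constructed wells and honours the merge rule", {
  # analytic surfaces: one weighted pseudo-frame per bin, with a density
  # floor so the whole grid is connected below the cap
  grid <- expand.grid(x = seq(0.25, 9.75, 0.5), y = seq(0.25, 9.75, 0.5))
  well_fel <- function(centers, width = 1) {
    w <- Reduce(`+`, lapply(centers, function(ctr) {
      exp(-((grid$x - ctr[1L])^2 + (grid$y - ctr[2L])^2) / (2 * width^2))
    })) + 1e-4
    weighted_fel(cv_from_points(grid$x, grid$y, w = w),
                 ax("d_com", 0, 10, 0.5), ax("n_native", 0, 10, 0.5))
  }
  fel2w <- well_fel(list(c(2, 2), c(8, 8)))
  barrier <- kB * 300 * log((1 + 1e-4) / (2 * exp(-18 / 2) + 1e-4))  # ~ 22 kT
  b <- find_basins(fel2w, energy_cap = barrier + 5, merge_barrier = 2)
  expect_equal(nrow(b$minima), 2L)
  expect_equal(sort(b$minima$cv1), c(2.25, 8.25), tolerance = 0.3)
  expect_equal(b$minima$f_min, c(0, 0), tolerance = 1e-6)
  # every assigned bin descends to its own basin minimum
  expect_true(all(!is.na(b$labels[cbind(b$minima$bin1, b$minima$bin2)])))
  # a merge barrier above the inter-well barrier collapses the two wells
  b1 <- find_basins(fel2w, energy_cap = barrier + 5,
                    merge_barrier = barrier + 1)
  expect_equal(nrow(b1$minima), 1L)
  # single well
  expect_equal(nrow(find_basins(well_fel(list(c(5, 5))), 30, 2)$minima), 1L)
  # three wells in a row
  fel3w <- well_fel(list(c(1.5, 5), c(5, 5), c(8.5, 5)), width = 0.7)
  expect_equal(nrow(find_basins(fel3w, 40, 2)$minima), 3L)
  expect_error(find_basins(fel2w, energy_cap = -1), "energy_cap")
})

test_that("frames map to the basin of their bin, or stay unassigned", {
  set.seed(93)
  n <- 2000
  x <- c(rnorm(n, 2, 0.4), rnorm(n, 8, 0.4))
  y <- c(rnorm(n, 2, 0.4), rnorm(n, 8, 0.4))
  cv <- cv_from_points(x, y)
  fel <- weighted_fel(cv, ax("d_com", 0, 10, 0.5), ax("n_native", 0, 10, 0.5))
  basins <- find_basins(fel, 15, 2)
  labels <- assign_states(cv, basins)
  truth <- rep(1:2, each = n)
  # map basin ids to ground truth by majority and demand near-perfect recovery
  tab <- table(truth, labels)
  acc <- sum(apply(tab, 2L, max)) / sum(tab)
  expect_gte(acc, 0.95)
  # a frame exactly at a minimum bin gets that basin
  m <- basins$minima
  at_min <- cv_from_points(m$cv1, m$cv2)
  expect_equal(assign_states(at_min, basins), m$label)
  # out-of-range or above-cap frames are unassigned, with a warning
  expect_warning(lab2 <- assign_states(cv_from_points(c(2, 99), c(2, 99)),
                                       basins), "unassigned")
  expect_false(is.na(lab2[1L]))
  expect_true(is.na(lab2[2L]))
})

test_that("indicator projections recover bin-wise conditional probabilities", {
  set.seed(94)
  n <- 6000
  x <- runif(n, 0, 10); y <- runif(n, 0, 10)
  cv <- cv_from_points(x, y)
  fel <- weighted_fel(cv, ax("d_com", 0, 10, 1), ax("n_native", 0, 10, 1))
  # constant-true indicator
  proj1 <- project_indicator(cv, rep(TRUE, n), fel, energy_cap = 1e6)
  expect_true(all(proj1[is.finite(fel$f)] == 1))
  # left-half step indicator
  ind <- x < 5
  proj <- project_indicator(cv, ind, fel, energy_cap = 1e6)
  expect_true(all(proj[1:5, ] == 1))
  expect_true(all(proj[6:10, ] == 0))
  # bin-dependent probability p = cx/10 recovered within 3 binomial SE for
  # well-populated bins
  p_bin <- (floor(x) + 0.5) / 10
  ind2 <- runif(n) < p_bin
  proj2 <- project_indicator(cv, ind2, fel, energy_cap = 1e6)
  counts <- fel$p * n
  for (i in 1:10) {
    p_hat <- mean(proj2[i, ])
    n_row <- sum(counts[i, ])
    p_true <- (i - 0.5) / 10
    expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n_row) + 1e-9)
  }
  # masking above the cap
  projm <- project_indicator(cv, ind, fel, energy_cap = 0.5)
  expect_true(anyNA(projm))
  expect_true(all(is.na(projm[fel$f >= 0.5])))
  expect_error(project_indicator(cv, ind[-1L], fel), "one value per frame")
})

test_that("cluster reweighting reproduces closed forms and is shift-invariant", {
  # equal free energies: arithmetic mean
  ct <- cluster_table(1:2, c(3, 3), c(1, 3), temperature = 300)
  expect_equal(reweighted_observable(ct), 2)
  # dF = kT log 2 with O = (0, 1): weights 2:1 -> <O> = 1/3
  ct2 <- cluster_table(1:2, c(0, kB * 300 * log(2)), c(0, 1), temperature = 300)
  expect_equal(reweighted_observable(ct2), 1 / 3, tolerance = 1e-12)
  # adding any constant to all F leaves the average unchanged
  ct3 <- ct2; ct3$f_alpha <- ct3$f_alpha + 123.456
  expect_equal(reweighted_observable(ct3), reweighted_observable(ct2),
               tolerance = 1e-12)
  # single cluster returns its own observable
  expect_equal(reweighted_observable(cluster_table(1L, 5, 7.7)), 7.7)
  # 50 random clusters vs the direct unstabilised evaluation
  ct50 <- generate_cluster_table(50L, f_range = c(0, 25), o_rule = "random",
                                 seed = 17)
  w <- exp(-ct50$f_alpha / (kB * 300))
  direct <- sum(ct50$o_alpha * w) / sum(w)
  expect_equal(reweighted_observable(ct50), direct, tolerance = 1e-10)
  # constant observable is returned exactly
  ctc <- generate_cluster_table(20L, o_rule = "constant", o_value = 4.2,
                                seed = 18)
  expect_equal(reweighted_observable(ctc), 4.2)
  expect_error(reweighted_observable(ct2, temperature = -1), "> 0")
})

test_that("state-conditioned maps reduce to the unconditional map for one state", {
  ref <- demo_reference()
  ncs <- native_contacts_from_reference(ref, "A", "B")
  mix <- state_mixture(c("F", "B"), c(0.5, 0.5), d_mean = c(40, 19),
                       d_sd = c(2, 0.5), q_mean = c(0, 0.8), q_sd = c(0, 0.05))
  g <- generate_complex_ensemble(ref, mix, n_frames = 40L, seed = 23)
  labels <- rep(1L, 40L)
  maps <- state_contact_map(g$ensemble, labels, 1L, ncs)
  full <- contact_probability(g$ensemble, atom_selection(chains = "A"),
                              atom_selection(chains = "B"), d_c = 4.5)
  expect_equal(maps$native$p + maps$nonnative$p, full$p)
  # native map carries probability only on native pairs
  nat_pairs <- matrix(FALSE, length(full$rows), length(full$cols),
                      dimnames = list(full$rows, full$cols))
  nat_pairs[cbind(match(ncs$res_a, full$rows), match(ncs$res_b, full$cols))] <- TRUE
  expect_true(all(maps$native$p[!nat_pairs] == 0))
  # a single-frame state yields binary maps
  m1 <- state_contact_map(g$ensemble, c(1L, rep(NA, 39L)), 1L, ncs)
  expect_true(all(m1$native$p %in% c(0, 1)))
  expect_error(state_contact_map(g$ensemble, labels, 7L, ncs), "no frames")
})
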