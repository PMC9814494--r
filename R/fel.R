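# Weighted 2D free-energy landscapes over collective-variable pairs,
# basin detection on the bin graph, per-frame state assignment,
# state-conditioned observables, and Boltzmann reweighting of cluster
# observables.
#
# F(bin) = -kB T ln P(bin), min-shifted to zero; empty bins are +Inf.

#' Define one landscape axis
#'
#' @param name collective-variable name (a column of the CV table).
#' @param min,max axis range; frames outside \[min, max) are dropped from
#'   the histogram (and left unassigned by [assign_states()]).
#' @param width bin width (> 0) in the CV's units.
#' @return object of class `fel_axis`.
#' @export
fel_axis <- function(name, min, max, width) {
  if (!is.finite(width) || width <= 0) stop("bin width must be > 0")
  if (max <= min) stop("axis max must exceed min")
  n <- ceiling((max - min) / width - 1e-9)
  structure(list(name = name, min = min, max = min + n * width,
                 width = width, n = as.integer(n)),
            class = "fel_axis")
}

.axis_bin <- function(axis, x) {
  b <- floor((x - axis$min) / axis$width) + 1L
  b[x < axis$min | b > axis$n] <- NA_integer_
  as.integer(b)
}

.axis_centers <- function(axis) axis$min + (seq_len(axis$n) - 0.5) * axis$width

#' Weighted 2D free-energy landscape
#'
#' Bins the frames of a CV table on two axes with their statistical
#' weights, converts bin probabilities to free energies
#' `F = -kB T ln P` (kJ/mol), and shifts the global minimum to zero.
#' Empty bins are `+Inf`.  The binned probabilities are kept so the
#' Boltzmann inversion round-trips exactly.
#'
#' @param cv data frame with the two CV columns and (optionally) a
#'   `weight` column (default uniform).
#' @param axis1,axis2 [fel_axis()] specs naming columns of `cv`.
#' @param temperature temperature in Kelvin (default 300).
#' @return object of class `fel2d`: free-energy matrix `$f`
#'   (axis1 bins x axis2 bins), probabilities `$p`, axes, temperature.
#' @export
weighted_fel <- function(cv, axis1, axis2, temperature = 300) {
  stopifnot(inherits(axis1, "fel_axis"), inherits(axis2, "fel_axis"))
  w <- if (is.null(cv$weight)) rep(1, nrow(cv)) else cv$weight
  b1 <- .axis_bin(axis1, cv[[axis1$name]])
  b2 <- .axis_bin(axis2, cv[[axis2$name]])
  ok <- !is.na(b1) & !is.na(b2) & w > 0
  if (!any(ok)) stop("no frame with positive weight falls inside the axes")
  p <- matrix(0, axis1$n, axis2$n)
  tot <- rowsum(w[ok], group = (b2[ok] - 1L) * axis1$n + b1[ok])
  p[as.integer(rownames(tot))] <- tot[, 1L]
  p <- p / sum(p)
  f <- -KB_KJ_MOL_K * temperature * log(p)
  f <- f - min(f)
  structure(list(f = f, p = p, axis1 = axis1, axis2 = axis2,
                 temperature = temperature,
                 total_weight = sum(w[ok]), n_frames_used = sum(ok)),
            class = "fel2d")
}

#' @export
print.fel2d <- function(x, ...) {
  cat("<fel2d> ", x$axis1$name, " x ", x$axis2$name, ": ",
      x$axis1$n, " x ", x$axis2$n, " bins, T = ", x$temperature, " K, ",
      sum(is.finite(x$f)), " occupied bins, F range [0, ",
      sprintf("%.2f", max(x$f[is.finite(x$f)])), "] kJ/mol\n", sep = "")
  invisible(x)
}

#' Filled-contour display of a free-energy landscape
#' @param x a `fel2d`.
#' @param cap clip free energies above this value (kJ/mol) for display.
#' @param ... passed to [graphics::filled.contour()].
#' @export
plot.fel2d <- function(x, cap = 20, ...) {
  f <- pmin(x$f, cap)
  graphics::filled.contour(.axis_centers(x$axis1), .axis_centers(x$axis2), f,
                           xlab = x$axis1$name, ylab = x$axis2$name,
                           main = "free energy (kJ/mol)", ...)
  invisible(x)
}

# 8-connected neighbours of bin (i, j) on an n1 x n2 grid
.neighbours8 <- function(i, j, n1, n2) {
  di <- rep(-1:1, times = 3L); dj <- rep(-1:1, each = 3L)
  keep <- !(di == 0L & dj == 0L)
  ii <- i + di[keep]; jj <- j + dj[keep]
  ok <- ii >= 1L & ii <= n1 & jj >= 1L & jj <= n2
  cbind(ii[ok], jj[ok])
}

#' Detect basins on a free-energy landscape
#'
#' Local minima of the 8-connected bin graph below `energy_cap` seed the
#' basins; every bin below the cap is assigned to a basin by steepest
#' descent; finally, basins separated by a barrier lower than
#' `merge_barrier` (measured from the shallower minimum to the connecting
#' saddle) are merged into the deeper basin.  Bins at or above the cap are
#' left unassigned, mirroring the convention of displaying only states
#' below 20 kJ/mol.
#'
#' @param fel a [weighted_fel()] surface.
#' @param energy_cap kJ/mol; bins with `F >= energy_cap` are unassigned
#'   (default 20).
#' @param merge_barrier kJ/mol; minimum saddle height for two basins to
#'   stay distinct (default 3, about 1.2 kT at 300 K, suppressing
#'   bin-noise minima).
#' @return object of class `basin_set`: integer label matrix `$labels`
#'   (NA above cap), and `$minima` data frame (label, bin indices, CV
#'   centres, `f_min`, `n_bins`).
#' @export
find_basins <- function(fel, energy_cap = 20, merge_barrier = 3) {
  f <- fel$f
  n1 <- nrow(f); n2 <- ncol(f)
  if (energy_cap <= min(f)) stop("energy_cap must exceed the global minimum (0)")
  below <- which(f < energy_cap, arr.ind = TRUE)

  # steepest-descent target of every below-cap bin (memoised)
  dest <- matrix(NA_integer_, n1, n2)  # linear index of the local minimum
  descend <- function(i, j) {
    path <- integer(0)
    repeat {
      lin <- (j - 1L) * n1 + i
      if (!is.na(dest[lin])) break
      path <- c(path, lin)
      nb <- .neighbours8(i, j, n1, n2)
      fn <- f[nb]
      k <- which.min(fn)
      if (!length(k) || fn[k] >= f[lin]) { dest[lin] <<- lin; break }
      i <- nb[k, 1L]; j <- nb[k, 2L]
    }
    tgt <- dest[(j - 1L) * n1 + i]
    if (length(path)) dest[path] <<- tgt
    tgt
  }
  for (r in seq_len(nrow(below))) descend(below[r, 1L], below[r, 2L])

  mins <- sort(unique(dest[below]))
  # keep only minima themselves below the cap (descent cannot raise F, so
  # they always are) and merge by flooding in order of increasing F
  parent <- seq_along(mins)
  find_root <- function(k) { while (parent[k] != k) k <- parent[k]; k }
  fmin <- f[mins]
  ord <- below[order(f[below]), , drop = FALSE]
  lab_of <- function(lin) match(dest[lin], mins)
  seen <- matrix(FALSE, n1, n2)
  for (r in seq_len(nrow(ord))) {
    i <- ord[r, 1L]; j <- ord[r, 2L]
    lin <- (j - 1L) * n1 + i
    nb <- .neighbours8(i, j, n1, n2)
    nb_lin <- (nb[, 2L] - 1L) * n1 + nb[, 1L]
    nb_lab <- unique(vapply(nb_lin[seen[nb_lin]],
                            function(l) find_root(lab_of(l)), integer(1L)))
    here <- find_root(lab_of(lin))
    groups <- unique(c(here, nb_lab))
    if (length(groups) > 1L) {
      # this bin is (part of) the saddle between the touching basins
      for (g in groups[-1L]) {
        a <- find_root(groups[1L]); b <- find_root(g)
        if (a == b) next
        shallow <- if (fmin[a] > fmin[b]) a else b
        deep <- if (shallow == a) b else a
        if (f[lin] - fmin[shallow] < merge_barrier) {
          parent[shallow] <- deep
          groups[1L] <- deep
        } else {
          groups[1L] <- if (fmin[a] <= fmin[b]) a else b
        }
      }
    }
    seen[lin] <- TRUE
  }
  roots <- vapply(seq_along(mins), find_root, integer(1L))
  final <- sort(unique(roots))
  labels <- matrix(NA_integer_, n1, n2)
  labels[below] <- match(roots[match(dest[below], mins)], final)
  minima_lin <- mins[final]
  minima <- data.frame(
    label = seq_along(final),
    bin1 = (minima_lin - 1L) %% n1 + 1L,
    bin2 = (minima_lin - 1L) %/% n1 + 1L
  )
  minima$cv1 <- .axis_centers(fel$axis1)[minima$bin1]
  minima$cv2 <- .axis_centers(fel$axis2)[minima$bin2]
  minima$f_min <- f[minima_lin]
  minima$n_bins <- as.integer(table(factor(labels[below], levels = seq_along(final))))
  structure(list(labels = labels, minima = minima,
                 energy_cap = energy_cap, merge_barrier = merge_barrier,
                 axis1 = fel$axis1, axis2 = fel$axis2),
            class = "basin_set")
}

#' @export
print.basin_set <- function(x, ...) {
  cat("<basin_set> ", nrow(x$minima), " basin(s), cap ", x$energy_cap,
      " kJ/mol, merge barrier ", x$merge_barrier, " kJ/mol\n", sep = "")
  print(x$minima)
  invisible(x)
}

#' Assign ensemble frames to basins
#'
#' Each frame maps to the basin of its bin; frames outside the axis ranges
#' or in bins above the energy cap are `NA` (unassigned) with a warning.
#'
#' @param cv the CV table used to build the landscape.
#' @param basins a [find_basins()] result.
#' @return integer vector of basin labels (NA = unassigned), one per row
#'   of `cv`.
#' @export
assign_states <- function(cv, basins) {
  b1 <- .axis_bin(basins$axis1, cv[[basins$axis1$name]])
  b2 <- .axis_bin(basins$axis2, cv[[basins$axis2$name]])
  out <- rep(NA_integer_, nrow(cv))
  ok <- !is.na(b1) & !is.na(b2)
  out[ok] <- basins$labels[cbind(b1[ok], b2[ok])]
  if (anyNA(out)) {
    warning(sum(is.na(out)), " frame(s) unassigned (outside axes or above cap)")
  }
  out
}

#' State-conditioned native / non-native contact maps
#'
#' Contact probabilities over the frames of one state (reweighted within
#' the state), split into a native map (probability on native pairs only)
#' and a non-native map (all other inter-chain pairs).
#'
#' @param ensemble an [idp_ensemble()] of the complex.
#' @param labels per-frame state labels (from [assign_states()]).
#' @param state the label to condition on.
#' @param ncs the [native_contacts_from_reference()] set (also fixes the
#'   chains, atom class and cutoff).
#' @param d_c contact cutoff (defaults to the `ncs` cutoff).
#' @return list of two `contact_map`s, `native` and `nonnative`, on the
#'   full inter-chain residue grid.
#' @export
state_contact_map <- function(ensemble, labels, state, ncs,
                              d_c = attr(ncs, "cutoff")) {
  idx <- which(!is.na(labels) & labels == state)
  if (!length(idx)) stop("no frames in state ", state)
  sub <- subset_frames(ensemble, idx)
  chains <- attr(ncs, "chains")
  full <- contact_probability(sub,
                              atom_selection(chains = chains[1L],
                                             atoms = attr(ncs, "atoms")),
                              atom_selection(chains = chains[2L],
                                             atoms = attr(ncs, "atoms")),
                              d_c = d_c)
  native_mask <- matrix(FALSE, length(full$rows), length(full$cols),
                        dimnames = list(full$rows, full$cols))
  keep <- ncs$res_a %in% full$rows & ncs$res_b %in% full$cols
  native_mask[cbind(match(ncs$res_a[keep], full$rows),
                    match(ncs$res_b[keep], full$cols))] <- TRUE
  nat <- full; nat$p <- full$p * native_mask
  non <- full; non$p <- full$p * !native_mask
  list(native = nat, nonnative = non)
}

#' Project a per-frame indicator onto the landscape
#'
#' For every bin below the energy cap, the weighted fraction of that bin's
#' frames for which the indicator is true (e.g. HRC formed); bins at or
#' above the cap are masked `NA`.
#'
#' @param cv the CV table used to build the landscape.
#' @param indicator logical vector, one value per frame.
#' @param fel the [weighted_fel()] surface.
#' @param energy_cap mask bins with `F >= energy_cap` (kJ/mol, default 20).
#' @return matrix of conditional probabilities (axis1 bins x axis2 bins),
#'   `NA` where masked or empty.
#' @export
project_indicator <- function(cv, indicator, fel, energy_cap = 20) {
  if (length(indicator) != nrow(cv)) {
    stop("indicator must have one value per frame")
  }
  w <- if (is.null(cv$weight)) rep(1, nrow(cv)) else cv$weight
  b1 <- .axis_bin(fel$axis1, cv[[fel$axis1$name]])
  b2 <- .axis_bin(fel$axis2, cv[[fel$axis2$name]])
  ok <- !is.na(b1) & !is.na(b2) & w > 0
  lin <- (b2[ok] - 1L) * fel$axis1$n + b1[ok]
  wtot <- rowsum(w[ok], lin)
  wind <- rowsum(w[ok] * (indicator[ok] + 0), lin)
  out <- matrix(NA_real_, fel$axis1$n, fel$axis2$n)
  out[as.integer(rownames(wtot))] <- wind[, 1L] / wtot[, 1L]
  out[fel$f >= energy_cap] <- NA_real_
  out
}

#' Boltzmann-weighted average of a cluster observable
#'
#' The reweighted ensemble average over clusters of a free-energy profile,
#' \deqn{\langle O\rangle = \sum_\alpha O_\alpha e^{-F_\alpha/k_BT} /
#'       \sum_\alpha e^{-F_\alpha/k_BT},}
#' evaluated with max-shift (log-sum-exp) stabilisation, hence exactly
#' invariant under adding any constant to all \eqn{F_\alpha}.
#'
#' @param clusters a [cluster_table()] (carries the temperature).
#' @param temperature override the table's temperature (Kelvin).
#' @return the weighted average, a single number.
#' @export
reweighted_observable <- function(clusters,
                                  temperature = attr(clusters, "temperature")) {
  stopifnot(nrow(clusters) >= 1L)
  if (is.null(temperature)) temperature <- 300
  if (!is.finite(temperature) || temperature <= 0) stop("temperature must be > 0")
  beta_f <- clusters$f_alpha / (KB_KJ_MOL_K * temperature)
  s <- exp(-(beta_f - min(beta_f)))
  sum(clusters$o_alpha * s) / sum(s)
}
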