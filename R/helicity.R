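# Per-residue helicity from backbone dihedrals, expanding-window
# uncertainties, helix-axis geometry, and chemical-shift table comparison.
#
# A residue is helical when its (phi, psi) fall in the alpha window
# (phi in [-100, -30], psi in [-77, -17] degrees by default) AND it belongs
# to a run of at least `min_run` consecutive such residues.  Terminal
# residues lack one dihedral and are never helical.

# signed dihedral (degrees) for rows of four coordinate matrices
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  m1 <- cbind(n1[, 2] * b2[, 3] - n1[, 3] * b2[, 2],
              n1[, 3] * b2[, 1] - n1[, 1] * b2[, 3],
              n1[, 1] * b2[, 2] - n1[, 2] * b2[, 1])
  b2n <- sqrt(rowSums(b2 * b2))
  x <- rowSums(n1 * n2)
  y <- -rowSums(m1 * n2) / b2n
  atan2(y, x) * 180 / pi
}

#' Backbone phi/psi dihedrals of one chain
#'
#' @param structure an [idp_structure()].
#' @param chain chain id; `NULL` means the single chain present.
#' @return data frame with columns `resno`, `phi`, `psi` (degrees; `NA`
#'   at chain termini).
#' @export
backbone_dihedrals <- function(structure, chain = NULL) {
  a <- structure$atoms
  if (is.null(chain)) {
    chains <- unique(a$chain)
    if (length(chains) > 1L) stop("structure has several chains; give `chain`")
    chain <- chains
  }
  in_ch <- a$chain == chain
  resno <- sort(unique(a$resno[in_ch]))
  pick <- function(name) {
    i <- match(paste(chain, resno, name), paste(a$chain, a$resno, a$elety))
    if (anyNA(i)) {
      stop("missing backbone atom ", name, " in residue ", chain, ":",
           resno[which(is.na(i))[1L]])
    }
    structure$xyz[i, , drop = FALSE]
  }
  N <- pick("N"); CA <- pick("CA"); C <- pick("C")
  n <- length(resno)
  phi <- psi <- rep(NA_real_, n)
  if (n >= 2L) {
    i <- 2:n
    phi[i] <- .dihedral(C[i - 1L, , drop = FALSE], N[i, , drop = FALSE],
                        CA[i, , drop = FALSE], C[i, , drop = FALSE])
    j <- 1:(n - 1L)
    psi[j] <- .dihedral(N[j, , drop = FALSE], CA[j, , drop = FALSE],
                        C[j, , drop = FALSE], N[j + 1L, , drop = FALSE])
  }
  data.frame(resno = resno, phi = phi, psi = psi)
}

#' Assign alpha-helical residues in one conformer
#'
#' Dihedral-window rule: `phi` in `phi_window` and `psi` in `psi_window`,
#' and membership in a run of at least `min_run` consecutive such
#' residues.  This replaces hydrogen-bond-based assignment (DSSP/STRIDE)
#' with a self-contained, deterministic criterion.
#'
#' @inheritParams backbone_dihedrals
#' @param phi_window,psi_window inclusive (lo, hi) bounds in degrees.
#' @param min_run minimum run length (default 4).
#' @return named logical vector (names = residue numbers).
#' @export
assign_helix <- function(structure, chain = NULL,
                         phi_window = c(-100, -30),
                         psi_window = c(-77, -17),
                         min_run = 4L) {
  d <- backbone_dihedrals(structure, chain)
  in_win <- !is.na(d$phi) & !is.na(d$psi) &
    d$phi >= phi_window[1] & d$phi <= phi_window[2] &
    d$psi >= psi_window[1] & d$psi <= psi_window[2]
  r <- rle(in_win)
  r$values <- r$values & r$lengths >= min_run
  out <- inverse.rle(r)
  names(out) <- d$resno
  out
}

#' Per-residue helicity profile of an ensemble
#'
#' Weighted fraction of frames in which each residue is assigned helical.
#'
#' @param ensemble an [idp_ensemble()].
#' @inheritParams assign_helix
#' @return data frame of class `helicity_profile`: columns `chain`,
#'   `resno`, `helicity` (and `std` after
#'   [expanding_window_error()]).
#' @export
helicity <- function(ensemble, chain = NULL,
                     phi_window = c(-100, -30), psi_window = c(-77, -17),
                     min_run = 4L) {
  m <- helix_matrix(ensemble, chain, phi_window, psi_window, min_run)
  w <- ensemble$weights / sum(ensemble$weights)
  ch <- if (is.null(chain)) unique(ensemble$atoms$chain)[1L] else chain
  out <- data.frame(chain = ch, resno = as.integer(colnames(m)),
                    helicity = as.vector(crossprod(m, w)),
                    stringsAsFactors = FALSE)
  class(out) <- c("helicity_profile", "data.frame")
  out
}

#' Per-frame helix assignment matrix of an ensemble
#'
#' @inheritParams helicity
#' @return logical `n_frames x n_residues` matrix (column names = residue
#'   numbers).
#' @export
helix_matrix <- function(ensemble, chain = NULL,
                         phi_window = c(-100, -30), psi_window = c(-77, -17),
                         min_run = 4L) {
  rows <- lapply(seq_len(n_frames(ensemble)), function(i) {
    assign_helix(get_frame(ensemble, i), chain, phi_window, psi_window, min_run)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- names(rows[[1L]])
  m
}

#' Mean helicity over a residue region
#'
#' Unweighted mean of the per-residue helicities across the (inclusive)
#' region, e.g. the alpha-A (120-129) or alpha-B (134-144) segment.
#'
#' @param profile a [helicity()] profile.
#' @param region integer vector `c(start, end)` (inclusive) or a full set
#'   of residue numbers.
#' @return mean helicity in \[0, 1\].
#' @export
region_helicity <- function(profile, region) {
  if (length(region) == 2L) region <- seq(region[1L], region[2L])
  sel <- profile$resno %in% region
  if (!any(sel) || !all(region %in% profile$resno)) {
    stop("region not fully contained in the helicity profile")
  }
  mean(profile$helicity[sel])
}

#' Expanding-window uncertainty of the helicity profile
#'
#' Frame order is treated as time order.  Helicity is recomputed on
#' `n_windows` expanding prefixes whose endpoints are evenly spaced over
#' the final third of the trajectory (e.g. frames 220, 240, 260, 280, 300
#' of a 300-frame ensemble with `n_windows = 5`); the per-residue standard
#' deviation across those estimates is returned.
#'
#' @inheritParams helicity
#' @param n_windows number of expanding prefixes (>= 2).
#' @return the helicity profile of the full ensemble with an added `std`
#'   column.
#' @export
expanding_window_error <- function(ensemble, chain = NULL, n_windows = 5L,
                                   phi_window = c(-100, -30),
                                   psi_window = c(-77, -17), min_run = 4L) {
  n <- n_frames(ensemble)
  if (n_windows < 2L) stop("n_windows must be >= 2")
  if (n < n_windows) stop("too few frames (", n, ") for ", n_windows, " windows")
  ends <- round(n * 2 / 3 + seq_len(n_windows) * (n / 3) / n_windows)
  ends <- pmax(ends, 1L)
  m <- helix_matrix(ensemble, chain, phi_window, psi_window, min_run)
  w <- ensemble$weights
  est <- sapply(ends, function(k) {
    wk <- w[seq_len(k)]
    as.vector(crossprod(m[seq_len(k), , drop = FALSE], wk / sum(wk)))
  })
  wall <- w / sum(w)
  ch <- if (is.null(chain)) unique(ensemble$atoms$chain)[1L] else chain
  prof <- data.frame(chain = ch, resno = as.integer(colnames(m)),
                     helicity = as.vector(crossprod(m, wall)),
                     std = apply(est, 1L, stats::sd),
                     stringsAsFactors = FALSE)
  class(prof) <- c("helicity_profile", "data.frame")
  attr(prof, "window_ends") <- ends
  prof
}

#' Best-fit helix axis of a residue region
#'
#' Principal axis of the region's C-alpha coordinates (total least
#' squares), oriented N-to-C: the returned unit vector has a positive
#' projection on the first-to-last C-alpha displacement.
#'
#' @param structure an [idp_structure()].
#' @param region `c(start, end)` residue numbers (inclusive), >= 4 CA atoms.
#' @param chain chain id; `NULL` means the single chain present.
#' @return unit 3-vector.
#' @export
helix_axis <- function(structure, region, chain = NULL) {
  a <- structure$atoms
  if (is.null(chain)) {
    chains <- unique(a$chain)
    if (length(chains) > 1L) stop("structure has several chains; give `chain`")
    chain <- chains
  }
  if (length(region) == 2L) region <- seq(region[1L], region[2L])
  idx <- select_atoms(structure,
                      atom_selection(chains = chain, residues = region,
                                     atoms = "alpha-carbon"),
                      warn_empty = FALSE)
  if (length(idx) < 4L) stop("helix region needs >= 4 C-alpha atoms")
  X <- structure$xyz[idx, , drop = FALSE]
  Xc <- sweep(X, 2L, colMeans(X))
  if (all(abs(Xc) < 1e-8)) stop("degenerate region: coincident C-alpha atoms")
  v <- svd(Xc, nu = 0L, nv = 1L)$v[, 1L]
  disp <- X[nrow(X), ] - X[1L, ]
  if (sum(v * disp) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Angle between two helix axes
#'
#' Angle in degrees between the N-to-C oriented best-fit axes of two
#' regions (e.g. the alpha-A / alpha-B inter-helix angle).
#'
#' @inheritParams helix_axis
#' @param regionA,regionB residue ranges (see [helix_axis()]).
#' @return angle in \[0, 180\] degrees.
#' @export
interhelix_angle <- function(structure, regionA, regionB, chain = NULL) {
  u <- helix_axis(structure, regionA, chain)
  v <- helix_axis(structure, regionB, chain)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' RMSE between predicted and experimental chemical shifts
#'
#' Root-mean-square difference over the residues common to both tables for
#' one nucleus (e.g. `CA`, `HA`).
#'
#' @param predicted,experimental shift tables (see [read_shift_table()]).
#' @param nucleus nucleus label to compare.
#' @return list with `rmse` (ppm), `n_residues` used, and `nucleus`.
#' @export
shift_rmse <- function(predicted, experimental, nucleus) {
  nucleus <- toupper(nucleus)
  p <- predicted[predicted$nucleus == nucleus, ]
  e <- experimental[experimental$nucleus == nucleus, ]
  common <- intersect(p$residue, e$residue)
  if (!length(common)) stop("no common residues for nucleus ", nucleus)
  dp <- p$shift[match(common, p$residue)] - e$shift[match(common, e$residue)]
  list(rmse = sqrt(mean(dp^2)), n_residues = length(common), nucleus = nucleus)
}
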