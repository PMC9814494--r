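# Containers for single conformers and conformational ensembles.
#
# A `idp_structure` is a list with
#   $atoms : data.frame(eleno, elety, resid, chain, resno, elesy)
#   $xyz   : n_atoms x 3 numeric matrix (angstrom)
# An `idp_ensemble` shares one $atoms table across frames and stores
#   $xyz   : n_frames x (3 * n_atoms) matrix (x1,y1,z1,x2,... per row,
#            the bio3d convention)
#   $weights : non-negative per-frame statistical weights (sum > 0)

#' Construct a single-conformer structure
#'
#' @param atoms data frame with columns `eleno` (atom serial), `elety`
#'   (atom name), `resid` (3-letter residue code), `chain` (single
#'   character), `resno` (residue number, as in the source file) and
#'   optionally `elesy` (element symbol; inferred from `elety` if absent).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in angstrom.
#' @return object of class `idp_structure`.
#' @export
idp_structure <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as.matrix(xyz)
  if (is.null(atoms$elesy) || all(is.na(atoms$elesy)) ||
      all(!nzchar(trimws(as.character(atoms$elesy))))) {
    atoms$elesy <- element_from_name(atoms$elety)
  } else {
    blank <- is.na(atoms$elesy) | !nzchar(trimws(atoms$elesy))
    atoms$elesy[blank] <- element_from_name(atoms$elety[blank])
    atoms$elesy <- toupper(trimws(atoms$elesy))
  }
  s <- structure(list(atoms = atoms, xyz = xyz), class = "idp_structure")
  validate_structure(s)
  s
}

#' @keywords internal
validate_structure <- function(s) {
  a <- s$atoms
  need <- c("elety", "resid", "chain", "resno", "elesy")
  miss <- setdiff(need, names(a))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.matrix(s$xyz) || ncol(s$xyz) != 3L || nrow(s$xyz) != nrow(a)) {
    stop("xyz must be an n_atoms x 3 matrix matching the atom table")
  }
  if (!all(is.finite(s$xyz))) stop("non-finite coordinates in structure")
  key <- paste(a$chain, a$resno, a$elety)
  if (anyDuplicated(key)) {
    stop("duplicate atom identity (chain, residue, name): ",
         key[duplicated(key)][1L])
  }
  for (ch in unique(a$chain)) {
    r <- a$resno[a$chain == ch]
    if (is.unsorted(r)) {
      stop("residue numbers not non-decreasing within chain ", ch)
    }
  }
  invisible(s)
}

#' Construct a weighted conformational ensemble
#'
#' All frames share one topology (atom names, elements, residue and chain
#' labels); only coordinates differ.
#'
#' @param atoms shared atom table (see [idp_structure()]).
#' @param xyz either an `n_frames x (3 * n_atoms)` matrix (bio3d row
#'   convention) or a list of `n_atoms x 3` matrices.
#' @param weights per-frame statistical weights; default uniform.  Must be
#'   non-negative with a positive sum.
#' @return object of class `idp_ensemble`.
#' @export
idp_ensemble <- function(atoms, xyz, weights = NULL) {
  if (is.list(xyz) && !is.matrix(xyz)) {
    xyz <- do.call(rbind, lapply(xyz, function(m) as.vector(t(m))))
  }
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L) stop("ensemble must contain at least one frame")
  atoms <- idp_structure(atoms, matrix(xyz[1L, ], ncol = 3L, byrow = TRUE))$atoms
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stop("xyz width does not match 3 * n_atoms")
  }
  if (is.null(weights)) weights <- rep(1, nrow(xyz))
  e <- structure(list(atoms = atoms, xyz = xyz, weights = as.numeric(weights)),
                 class = "idp_ensemble")
  validate_ensemble(e)
  e
}

#' @keywords internal
validate_ensemble <- function(e) {
  if (!all(is.finite(e$xyz))) stop("non-finite coordinates in ensemble")
  w <- e$weights
  if (length(w) != nrow(e$xyz)) stop("weights length must equal frame count")
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  if (sum(w) <= 0) stop("weights must have a positive sum")
  invisible(e)
}

#' Number of frames in an ensemble
#' @param e an `idp_ensemble`.
#' @export
n_frames <- function(e) {
  stopifnot(inherits(e, "idp_ensemble"))
  nrow(e$xyz)
}

#' Number of atoms in a structure or ensemble
#' @param x an `idp_structure` or `idp_ensemble`.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Extract one frame of an ensemble as a structure
#' @param e an `idp_ensemble`.
#' @param i frame index (1-based).
#' @return an `idp_structure`.
#' @export
get_frame <- function(e, i) {
  stopifnot(inherits(e, "idp_ensemble"), i >= 1L, i <= n_frames(e))
  structure(list(atoms = e$atoms,
                 xyz = matrix(e$xyz[i, ], ncol = 3L, byrow = TRUE)),
            class = "idp_structure")
}

#' Coordinates of frame i as an n_atoms x 3 matrix
#' @keywords internal
frame_coords <- function(e, i) matrix(e$xyz[i, ], ncol = 3L, byrow = TRUE)

#' Replace the per-frame weights of an ensemble
#' @param e an `idp_ensemble`.
#' @param weights new weight vector (length `n_frames(e)`, non-negative,
#'   positive sum).
#' @export
set_weights <- function(e, weights) {
  e$weights <- as.numeric(weights)
  validate_ensemble(e)
  e
}

#' Restrict an ensemble to a subset of frames
#' @param e an `idp_ensemble`.
#' @param idx frame indices to keep.
#' @export
subset_frames <- function(e, idx) {
  idp_ensemble(e$atoms, e$xyz[idx, , drop = FALSE], e$weights[idx])
}

#' @export
print.idp_structure <- function(x, ...) {
  a <- x$atoms
  cat("<idp_structure> ", nrow(a), " atoms, ",
      length(unique(paste(a$chain, a$resno))), " residues, chains: ",
      paste(unique(a$chain), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
print.idp_ensemble <- function(x, ...) {
  uni <- length(unique(x$weights)) == 1L
  cat("<idp_ensemble> ", n_frames(x), " frames x ", n_atoms(x), " atoms; ",
      if (uni) "uniform weights" else "non-uniform weights", "\n", sep = "")
  print(get_frame(x, 1L))
  invisible(x)
}
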