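# Residue-residue contacts.  Two residues are in contact when the minimum
# distance between any two selected heavy atoms in different residues is
# strictly below the cutoff (default 4.5 A).

#' @keywords internal
.pair_dist2 <- function(X, Y) {
  # squared Euclidean distances between rows of X and rows of Y
  d2 <- matrix(rowSums(X * X), nrow(X), nrow(Y)) +
    matrix(rowSums(Y * Y), nrow(X), nrow(Y), byrow = TRUE) -
    2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  d2
}

# 0/1 residue-membership matrix: n_res x n_atoms
.membership <- function(res_fac) {
  m <- matrix(0L, nlevels(res_fac), length(res_fac))
  m[cbind(as.integer(res_fac), seq_along(res_fac))] <- 1L
  m
}

# Per-residue-pair counts of atom pairs within cutoff, for one frame.
# Returns an n_resA x n_resB integer matrix with residue labels as dimnames.
.residue_pair_counts <- function(coords, atoms, idxA, idxB, d_c) {
  labA <- factor(residue_labels(atoms, idxA), levels = unique(residue_labels(atoms, idxA)))
  labB <- factor(residue_labels(atoms, idxB), levels = unique(residue_labels(atoms, idxB)))
  ind <- .pair_dist2(coords[idxA, , drop = FALSE],
                     coords[idxB, , drop = FALSE]) < d_c^2
  cnt <- .membership(labA) %*% (ind + 0L) %*% t(.membership(labB))
  dimnames(cnt) <- list(levels(labA), levels(labB))
  cnt
}

# Resolve contact mode and the mask of excluded residue pairs.
# Returns list(kind, mask) where mask is TRUE for pairs to keep.
.contact_mask <- function(atoms, idxA, idxB, exclude_neighbors) {
  labA <- unique(residue_labels(atoms, idxA))
  labB <- unique(residue_labels(atoms, idxB))
  overlap <- intersect(labA, labB)
  if (length(overlap)) {
    chains <- unique(atoms$chain[c(idxA, idxB)])
    if (length(chains) > 1L) {
      stop("selections overlap at the residue level across chains; ",
           "intra-chain mode requires a single chain")
    }
    kind <- "intra"
  } else {
    kind <- "inter"
  }
  resnoA <- atoms$resno[idxA][!duplicated(residue_labels(atoms, idxA))]
  resnoB <- atoms$resno[idxB][!duplicated(residue_labels(atoms, idxB))]
  mask <- matrix(TRUE, length(labA), length(labB), dimnames = list(labA, labB))
  if (kind == "intra") {
    sep <- abs(outer(resnoA, resnoB, "-"))
    mask[sep <= exclude_neighbors] <- FALSE
  }
  list(kind = kind, mask = mask, resnoA = resnoA, resnoB = resnoB)
}

#' Residue pairs in contact within one conformer
#'
#' A pair `(r1, r2)` is reported iff the minimum over selected atom pairs of
#' the Euclidean distance is strictly `< d_c`.  If the two selections
#' overlap at the residue level the computation runs in intra-chain mode
#' and pairs with `|i - j| <= exclude_neighbors` are dropped (nearest
#' neighbours are trivially in contact); otherwise inter-chain mode with no
#' exclusion.
#'
#' @param structure an [idp_structure()].
#' @param selA,selB [atom_selection()]s (typically side-chain heavy atoms).
#' @param d_c distance cutoff in angstrom (default 4.5).
#' @param exclude_neighbors sequence-separation exclusion for intra-chain
#'   maps (default 1).
#' @return data frame with one row per contacting residue pair: columns
#'   `res_a`, `res_b` ("chain:resno" labels), `n_atom_pairs` (number of
#'   selected atom pairs within the cutoff).  Intra-chain pairs are stored
#'   once with `resno_a < resno_b`.
#' @export
frame_contacts <- function(structure, selA, selB, d_c = 4.5,
                           exclude_neighbors = 1L) {
  idxA <- select_atoms(structure, selA, warn_empty = FALSE)
  idxB <- select_atoms(structure, selB, warn_empty = FALSE)
  if (!length(idxA) || !length(idxB)) stop("empty atom selection")
  cm <- .contact_mask(structure$atoms, idxA, idxB, exclude_neighbors)
  cnt <- .residue_pair_counts(structure$xyz, structure$atoms, idxA, idxB, d_c)
  cnt[!cm$mask] <- 0L
  if (cm$kind == "intra") {
    upper <- outer(cm$resnoA, cm$resnoB, "<")
    cnt[!upper] <- 0L
  }
  hit <- which(cnt > 0L, arr.ind = TRUE)
  data.frame(res_a = rownames(cnt)[hit[, 1L]],
             res_b = colnames(cnt)[hit[, 2L]],
             n_atom_pairs = cnt[hit],
             stringsAsFactors = FALSE)
}

#' Construct a contact-probability map object
#' @keywords internal
new_contact_map <- function(p, kind, cutoff = NA_real_) {
  stopifnot(is.matrix(p))
  structure(list(p = p, rows = rownames(p), cols = colnames(p),
                 kind = kind, cutoff = cutoff),
            class = "contact_map")
}

#' Weighted contact-probability map over an ensemble
#'
#' Entry `(r1, r2)` is the weighted fraction of frames in which the residue
#' pair is in contact (weights normalised internally, so any uniform
#' rescaling of the weights leaves the map unchanged).
#'
#' @inheritParams frame_contacts
#' @param ensemble an [idp_ensemble()].
#' @return object of class `contact_map`: probability matrix `$p` in
#'   \[0, 1\] with "chain:resno" dimnames, `$kind` `"intra"` (symmetric) or
#'   `"inter"` (rectangular).
#' @export
contact_probability <- function(ensemble, selA, selB, d_c = 4.5,
                                exclude_neighbors = 1L) {
  idxA <- select_atoms(ensemble, selA, warn_empty = FALSE)
  idxB <- select_atoms(ensemble, selB, warn_empty = FALSE)
  if (!length(idxA) || !length(idxB)) stop("empty atom selection")
  cm <- .contact_mask(ensemble$atoms, idxA, idxB, exclude_neighbors)
  w <- ensemble$weights / sum(ensemble$weights)
  acc <- matrix(0, nrow(cm$mask), ncol(cm$mask), dimnames = dimnames(cm$mask))
  for (i in seq_len(n_frames(ensemble))) {
    if (w[i] == 0) next
    cnt <- .residue_pair_counts(frame_coords(ensemble, i), ensemble$atoms,
                                idxA, idxB, d_c)
    acc <- acc + w[i] * (cnt > 0L)
  }
  acc[!cm$mask] <- 0
  if (cm$kind == "intra" && identical(rownames(acc), colnames(acc))) {
    acc <- pmax(acc, t(acc))  # guard: symmetric by construction when selA == selB
  }
  new_contact_map(acc, cm$kind, cutoff = d_c)
}

#' Difference between two contact maps
#'
#' Elementwise `mapA - mapB` (e.g. phosphorylated minus unphosphorylated
#' free-state maps).  Requires identical residue labels.
#'
#' @param mapA,mapB `contact_map` objects with identical row/column labels.
#' @return a `contact_map` of kind `"delta"` with entries in \[-1, 1\].
#' @export
delta_contact <- function(mapA, mapB) {
  stopifnot(inherits(mapA, "contact_map"), inherits(mapB, "contact_map"))
  bad <- c(setdiff(mapA$rows, mapB$rows), setdiff(mapB$rows, mapA$rows),
           setdiff(mapA$cols, mapB$cols), setdiff(mapB$cols, mapA$cols))
  if (length(bad) || !identical(mapA$rows, mapB$rows) ||
      !identical(mapA$cols, mapB$cols)) {
    stop("contact maps are not aligned; unmatched residues: ",
         paste(unique(bad), collapse = ", "))
  }
  new_contact_map(mapA$p - mapB$p, "delta", cutoff = mapA$cutoff)
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", x$kind, ", ", length(x$rows), " x ", length(x$cols),
      " residues; value range [", sprintf("%.3f", min(x$p)), ", ",
      sprintf("%.3f", max(x$p)), "]\n", sep = "")
  invisible(x)
}

#' Heat-map display of a contact map
#' @param x a `contact_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.contact_map <- function(x, ...) {
  graphics::image(seq_along(x$rows), seq_along(x$cols), x$p,
                  xlab = "residue (rows)", ylab = "residue (cols)",
                  main = paste0(x$kind, " contact map"), ...)
  invisible(x)
}

#' Write a contact map as CSV
#'
#' Matrix layout: header row of column residue labels, first column the row
#' residue labels.  Values are formatted at 6 significant digits so reruns
#' are byte-identical.
#'
#' @param map a `contact_map`.
#' @param path output CSV path.
#' @export
write_contact_map <- function(map, path) {
  m <- map$p
  out <- data.frame(residue = rownames(m),
                    apply(m, 2L, fmt_num),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("residue", colnames(m))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
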