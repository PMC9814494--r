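# The hydrophobic-residue-cluster (HRC) order parameter: the number of
# side-chain heavy-atom contact pairs among a small set of designated
# hydrophobic residues.  A conformer whose count is strictly greater than
# the threshold (default 15) carries a formed HRC.

#' Specify the HRC order parameter
#'
#' Defaults follow the pKID convention: the four hydrophobic residues
#' 128, 134, 137 and 138 flanking the phosphorylation site, a 4.5-A
#' side-chain heavy-atom cutoff, and the strict `count > 15` rule.  The
#' residue set is fully configurable (e.g. threshold 8 for the
#' unphosphorylated-peptide comparison).
#'
#' @param residues integer vector of residue numbers forming the cluster
#'   (at least 2).
#' @param chain chain id holding the residues; `NULL` means the (single)
#'   chain of the structure at evaluation time.
#' @param cutoff contact cutoff `d_c` in angstrom (> 0, default 4.5).
#' @param threshold count threshold `n_min` (>= 0, default 15); a frame is
#'   HRC iff count `> threshold`, strictly.
#' @param mode `"pairs"` counts inter-residue atom pairs within the cutoff
#'   (default); `"atoms"` counts distinct atoms involved in at least one
#'   inter-residue contact.
#' @return object of class `hrc_spec`.
#' @export
hrc_spec <- function(residues = c(128L, 134L, 137L, 138L), chain = NULL,
                     cutoff = 4.5, threshold = 15L,
                     mode = c("pairs", "atoms")) {
  mode <- match.arg(mode)
  residues <- as.integer(residues)
  if (length(residues) < 2L) stop("HRC residue set must have >= 2 residues")
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  if (threshold < 0) stop("threshold must be >= 0")
  structure(list(residues = residues, chain = chain, cutoff = cutoff,
                 threshold = as.integer(threshold), mode = mode),
            class = "hrc_spec")
}

# side-chain heavy atom indices of the spec residues, split by residue
.hrc_atoms <- function(x, spec) {
  chain <- spec$chain
  if (is.null(chain)) {
    chains <- unique(x$atoms$chain)
    if (length(chains) > 1L) {
      stop("structure has several chains; set `chain` in hrc_spec()")
    }
    chain <- chains
  }
  idx_by_res <- lapply(spec$residues, function(r) {
    select_atoms(x, atom_selection(chains = chain, residues = r,
                                   atoms = "side-chain-heavy"),
                 warn_empty = FALSE)
  })
  empty <- lengths(idx_by_res) == 0L
  if (any(empty)) {
    stop("HRC residue ", chain, ":", spec$residues[which(empty)[1L]],
         " is missing or has no side-chain heavy atoms")
  }
  idx_by_res
}

#' HRC contact count of one conformer
#'
#' Number of unordered side-chain heavy-atom pairs `(a, b)`, with `a` and
#' `b` in *different* residues of the HRC set, whose distance is strictly
#' below the cutoff.  With `mode = "atoms"` the number of distinct atoms
#' involved in at least one such contact is returned instead.
#'
#' @param structure an [idp_structure()].
#' @param spec an [hrc_spec()].
#' @return non-negative integer.
#' @export
hrc_contact_count <- function(structure, spec = hrc_spec()) {
  idx_by_res <- .hrc_atoms(structure, spec)
  idx <- unlist(idx_by_res)
  res_of <- rep(seq_along(idx_by_res), lengths(idx_by_res))
  X <- structure$xyz[idx, , drop = FALSE]
  ind <- .pair_dist2(X, X) < spec$cutoff^2
  cross <- outer(res_of, res_of, "!=")
  hit <- ind & cross
  if (spec$mode == "pairs") as.integer(sum(hit) / 2L) else as.integer(sum(rowSums(hit) > 0L))
}

#' Is the HRC formed in this conformer?
#'
#' `TRUE` iff [hrc_contact_count()] is strictly greater than the spec's
#' threshold (`count > n_min`; a count exactly equal to the threshold is
#' not HRC).
#'
#' @inheritParams hrc_contact_count
#' @return logical scalar.
#' @export
is_hrc <- function(structure, spec = hrc_spec()) {
  hrc_contact_count(structure, spec) > spec$threshold
}

#' HRC formation probability over an ensemble
#'
#' Weighted fraction of frames whose HRC is formed; invariant under uniform
#' rescaling of the frame weights.
#'
#' @param ensemble an [idp_ensemble()].
#' @param spec an [hrc_spec()].
#' @return probability in \[0, 1\].
#' @export
hrc_probability <- function(ensemble, spec = hrc_spec()) {
  counts <- hrc_counts(ensemble, spec)
  w <- ensemble$weights / sum(ensemble$weights)
  sum(w[counts > spec$threshold])
}

#' Per-frame HRC contact counts of an ensemble
#' @inheritParams hrc_probability
#' @return integer vector, one count per frame.
#' @export
hrc_counts <- function(ensemble, spec = hrc_spec()) {
  idx_by_res <- .hrc_atoms(ensemble, spec)
  idx <- unlist(idx_by_res)
  res_of <- rep(seq_along(idx_by_res), lengths(idx_by_res))
  cross <- outer(res_of, res_of, "!=")
  vapply(seq_len(n_frames(ensemble)), function(i) {
    X <- frame_coords(ensemble, i)[idx, , drop = FALSE]
    hit <- (.pair_dist2(X, X) < spec$cutoff^2) & cross
    if (spec$mode == "pairs") as.integer(sum(hit) / 2L)
    else as.integer(sum(rowSums(hit) > 0L))
  }, integer(1L))
}

#' Weighted distribution of HRC contact counts
#'
#' @inheritParams hrc_probability
#' @return data frame with columns `count` (integer) and `probability`
#'   (weighted, sums to 1).
#' @export
hrc_count_distribution <- function(ensemble, spec = hrc_spec()) {
  counts <- hrc_counts(ensemble, spec)
  w <- ensemble$weights / sum(ensemble$weights)
  p <- vapply(split(w, counts), sum, numeric(1L))
  data.frame(count = as.integer(names(p)), probability = unname(p))
}
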