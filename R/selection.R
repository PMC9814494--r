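# Deterministic atom selections shared across the frames of an ensemble.

#' Define an atom selection
#'
#' A selection filters by chain, residue number, and atom class.  Applied to
#' an ensemble it always yields the same index set for every frame, because
#' frames share one topology.
#'
#' @param chains optional character vector of chain ids to keep.
#' @param residues optional integer vector (or range) of residue numbers to
#'   keep (numbering as in the source file).
#' @param atoms atom class: `"all-heavy"` (default), `"side-chain-heavy"`
#'   (heavy atoms excluding backbone N, CA, C, O and OXT), `"backbone"`
#'   (N, CA, C, O), or `"alpha-carbon"`.
#' @return object of class `atom_selection`.
#' @export
atom_selection <- function(chains = NULL, residues = NULL,
                           atoms = c("all-heavy", "side-chain-heavy",
                                     "backbone", "alpha-carbon")) {
  atoms <- match.arg(atoms)
  structure(list(chains = chains,
                 residues = if (is.null(residues)) NULL else as.integer(residues),
                 atoms = atoms),
            class = "atom_selection")
}

#' Apply a selection to a structure or ensemble
#'
#' Hydrogens are always excluded by *element* (not by name prefix), so
#' naming dialects do not matter.  Phosphoserine (SEP) phosphate atoms
#' count as side-chain heavy atoms.
#'
#' @param x an `idp_structure` or `idp_ensemble`.
#' @param sel an [atom_selection()].  A bare character string is accepted
#'   as shorthand for `atom_selection(atoms = sel)`.
#' @param warn_empty emit a warning when the selection is empty.
#' @return integer vector of atom indices (rows of `x$atoms`), in file order.
#' @export
select_atoms <- function(x, sel, warn_empty = TRUE) {
  if (is.character(sel)) sel <- atom_selection(atoms = sel)
  if (!inherits(sel, "atom_selection")) stop("unknown atom class / selection")
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chains)) keep <- keep & a$chain %in% sel$chains
  if (!is.null(sel$residues)) keep <- keep & a$resno %in% sel$residues
  heavy <- toupper(a$elesy) != "H"
  keep <- keep & switch(sel$atoms,
    "all-heavy"        = heavy,
    "side-chain-heavy" = heavy & !a$elety %in% BACKBONE_ATOMS,
    "backbone"         = a$elety %in% c("N", "CA", "C", "O"),
    "alpha-carbon"     = a$elety == "CA"
  )
  idx <- which(keep)
  if (length(idx) == 0L && warn_empty) {
    warning("selection matched no atoms")
  }
  idx
}

#' Residue labels ("chain:resno") for given atom rows
#' @keywords internal
residue_labels <- function(atoms, idx = seq_len(nrow(atoms))) {
  paste0(atoms$chain[idx], ":", atoms$resno[idx])
}
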