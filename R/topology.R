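# Standard amino-acid heavy-atom topology and physical constants.

# Backbone heavy atoms common to all residues (OXT only on C-termini).
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Side-chain heavy-atom names per residue type (PDB v3 naming).  SEP is
# phosphoserine; its phosphate P/O atoms count as side-chain heavy atoms.
SIDECHAIN_ATOMS <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  SEP = c("CB", "OG", "P", "O1P", "O2P", "O3P"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

# Standard atomic masses (u) for the elements occurring in proteins and
# common modifications.
ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  P = 30.973762, S = 32.06, SE = 78.971
)

# Boltzmann constant in kJ/(mol K).
KB_KJ_MOL_K <- 0.008314462618

#' Infer the chemical element from a PDB atom name
#'
#' Strips digits and primes from the atom name and matches the leading
#' character(s) against the elements found in proteins.  Used as a fallback
#' when a PDB file lacks element columns.
#'
#' @param name character vector of atom names (e.g. `"CA"`, `"OG1"`, `"1HB"`).
#' @return character vector of element symbols.
#' @keywords internal
element_from_name <- function(name) {
  stripped <- toupper(gsub("[0-9']", "", name))
  out <- substr(stripped, 1L, 1L)
  out[stripped == "SE"] <- "SE"
  bad <- !out %in% names(ATOMIC_MASS)
  if (any(bad)) {
    stop("cannot infer element for atom name(s): ",
         paste(unique(name[bad]), collapse = ", "))
  }
  out
}

#' Masses for a vector of element symbols
#' @keywords internal
mass_of_elements <- function(element) {
  m <- ATOMIC_MASS[toupper(element)]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Heavy-atom names for a residue type
#'
#' @param resid 3-letter residue code (e.g. `"LEU"`, `"SEP"`).
#' @param part one of `"all"`, `"sidechain"`, `"backbone"`.
#' @return character vector of atom names.
#' @examples
#' residue_heavy_atoms("LEU", "sidechain")  # CB CG CD1 CD2
#' @export
residue_heavy_atoms <- function(resid, part = c("all", "sidechain", "backbone")) {
  part <- match.arg(part)
  resid <- toupper(resid)
  if (!resid %in% names(SIDECHAIN_ATOMS)) {
    stop("unknown residue type: ", resid)
  }
  switch(part,
    all       = c(c("N", "CA", "C", "O"), SIDECHAIN_ATOMS[[resid]]),
    sidechain = SIDECHAIN_ATOMS[[resid]],
    backbone  = c("N", "CA", "C", "O")
  )
}
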