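# Binding collective variables: centre-of-mass distance between the two
# chains, native-contact count and fraction of native contacts Q against a
# reference bound complex, and native/non-native classification of the
# contacts formed in any conformer.

#' Native contacts of a reference bound complex
#'
#' All inter-chain residue pairs whose minimum selected-atom distance is
#' strictly below the cutoff in the reference structure.  These pairs are
#' the yardstick for `Q` and for native/non-native classification of
#' contacts in ensemble frames.
#'
#' @param reference an [idp_structure()] of the bound complex.
#' @param chainA,chainB chain ids (e.g. the IDP and its partner).
#' @param d_c contact cutoff in angstrom (default 4.5, strict `<`).
#' @param atoms atom class used for the contact rule (default
#'   `"all-heavy"`).
#' @return object of class `native_contact_set`: data frame of pairs
#'   (`res_a` on `chainA`, `res_b` on `chainB`) with attributes `cutoff`,
#'   `atoms`, `chains`.
#' @export
native_contacts_from_reference <- function(reference, chainA, chainB,
                                           d_c = 4.5, atoms = "all-heavy") {
  present <- unique(reference$atoms$chain)
  for (ch in c(chainA, chainB)) {
    if (!ch %in% present) stop("reference lacks chain ", ch)
  }
  pairs <- frame_contacts(reference,
                          atom_selection(chains = chainA, atoms = atoms),
                          atom_selection(chains = chainB, atoms = atoms),
                          d_c = d_c)
  if (nrow(pairs) == 0L) {
    stop("reference has no inter-chain contacts at ", d_c,
         " A; not a bound complex")
  }
  out <- pairs[, c("res_a", "res_b")]
  attr(out, "cutoff") <- d_c
  attr(out, "atoms") <- atoms
  attr(out, "chains") <- c(chainA, chainB)
  class(out) <- c("native_contact_set", "data.frame")
  out
}

#' Centre-of-mass distance between two selections
#'
#' Euclidean distance between the mass-weighted centroids of two atom
#' selections (standard atomic masses by element).
#'
#' @param structure an [idp_structure()].
#' @param selA,selB [atom_selection()]s (e.g. the heavy atoms of each
#'   chain).
#' @return distance in angstrom.
#' @export
com_distance <- function(structure, selA, selB) {
  com <- function(sel) {
    idx <- select_atoms(structure, sel, warn_empty = FALSE)
    if (!length(idx)) stop("empty atom selection in com_distance")
    m <- mass_of_elements(structure$atoms$elesy[idx])
    colSums(structure$xyz[idx, , drop = FALSE] * m) / sum(m)
  }
  sqrt(sum((com(selA) - com(selB))^2))
}

# inter-chain residue-pair contact labels for one structure
.interchain_contacts <- function(structure, ncs, d_c = attr(ncs, "cutoff")) {
  chains <- attr(ncs, "chains")
  frame_contacts(structure,
                 atom_selection(chains = chains[1L], atoms = attr(ncs, "atoms")),
                 atom_selection(chains = chains[2L], atoms = attr(ncs, "atoms")),
                 d_c = d_c)
}

#' Fraction of native contacts Q of one conformer
#'
#' `n_native` is the number of reference pairs currently in contact under
#' the same rule and cutoff used to define them; `Q = n_native /
#' |native set|`.
#'
#' @param structure an [idp_structure()] containing both reference chains.
#' @param ncs a [native_contacts_from_reference()] set.
#' @param d_c contact cutoff (defaults to the cutoff stored in `ncs`).
#' @return list with `q` in \[0, 1\] and integer `n_native`.
#' @export
q_fraction <- function(structure, ncs, d_c = attr(ncs, "cutoff")) {
  chains <- attr(ncs, "chains")
  ref_res <- unique(c(sub(":.*", "", ncs$res_a), sub(":.*", "", ncs$res_b)))
  lab <- residue_labels(structure$atoms)
  missing <- setdiff(c(ncs$res_a, ncs$res_b), lab)
  if (length(missing)) {
    stop("structure lacks residue(s) of the native set: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  cur <- .interchain_contacts(structure, ncs, d_c)
  formed <- paste(ncs$res_a, ncs$res_b) %in% paste(cur$res_a, cur$res_b)
  list(q = sum(formed) / nrow(ncs), n_native = sum(formed))
}

#' Binding collective-variable table of an ensemble
#'
#' One row per frame: centre-of-mass distance between the two chains'
#' heavy atoms, native-contact count, fraction of native contacts `Q`, and
#' the frame weight.
#'
#' @param ensemble an [idp_ensemble()] of the complex.
#' @param ncs a [native_contacts_from_reference()] set.
#' @param d_c contact cutoff (defaults to the `ncs` cutoff).
#' @return data frame with columns `frame`, `d_com`, `n_native`, `q`,
#'   `weight`.
#' @export
cv_table <- function(ensemble, ncs, d_c = attr(ncs, "cutoff")) {
  chains <- attr(ncs, "chains")
  selA <- atom_selection(chains = chains[1L], atoms = "all-heavy")
  selB <- atom_selection(chains = chains[2L], atoms = "all-heavy")
  key <- paste(ncs$res_a, ncs$res_b)
  n <- n_frames(ensemble)
  d_com <- numeric(n); n_native <- integer(n)
  for (i in seq_len(n)) {
    s <- get_frame(ensemble, i)
    d_com[i] <- com_distance(s, selA, selB)
    cur <- .interchain_contacts(s, ncs, d_c)
    n_native[i] <- sum(key %in% paste(cur$res_a, cur$res_b))
  }
  data.frame(frame = seq_len(n), d_com = d_com, n_native = n_native,
             q = n_native / nrow(ncs), weight = ensemble$weights)
}

#' Split a conformer's inter-chain contacts into native and non-native
#'
#' Partition of the currently formed inter-chain residue pairs by
#' membership in the native set; the union is exactly the inter-chain
#' [frame_contacts()] result.
#'
#' @inheritParams q_fraction
#' @return list of two data frames, `native` and `nonnative`, each with
#'   columns `res_a`, `res_b`.
#' @export
split_native_nonnative <- function(structure, ncs, d_c = attr(ncs, "cutoff")) {
  cur <- .interchain_contacts(structure, ncs, d_c)
  is_native <- paste(cur$res_a, cur$res_b) %in% paste(ncs$res_a, ncs$res_b)
  list(native = cur[is_native, c("res_a", "res_b")],
       nonnative = cur[!is_native, c("res_a", "res_b")])
}
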