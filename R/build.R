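# Internal-coordinate peptide builder.
#
# Chains are grown atom by atom with ideal bond lengths and angles (NeRF
# placement); backbone dihedrals are set per residue, so a residue's
# (phi, psi) equal its assigned values exactly.  Side chains are CB plus
# the residue's standard complement of heavy atoms placed as pseudo-atoms
# on a deterministic spiral off CB -- contact analysis only needs heavy-atom
# positions, not rotamer realism.

# ideal backbone geometry (angstrom / degrees)
.GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.53,
  a_n_ca_c = 111.0, a_ca_c_n = 116.6, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  a_n_ca_cb = 110.5, omega = 180
)

# place atom D bonded to C: |CD| = bond, angle(B,C,D) = angle_deg,
# dihedral(A,B,C,D) = dihedral_deg
.place_atom <- function(A, B, C, bond, angle_deg, dihedral_deg) {
  th <- angle_deg * pi / 180
  ph <- dihedral_deg * pi / 180
  d2 <- c(-bond * cos(th), bond * cos(ph) * sin(th), bond * sin(ph) * sin(th))
  bc <- .unit(C - B)
  n <- .unit(.cross(B - A, bc))
  M <- cbind(bc, .cross(n, bc), n)
  C + as.vector(M %*% d2)
}

# deterministic pseudo-side-chain offsets from CB, in the local frame
# (u = CA->CB direction): a tight outward spiral
.sidechain_offsets <- function(k) {
  if (k < 1L) return(matrix(0, 0L, 3L))
  j <- seq_len(k)
  cbind(0.35 * j, 1.0 * cos(2.4 * j), 1.0 * sin(2.4 * j))
}

#' Build a single peptide conformer from internal coordinates
#'
#' Helical residues get `(phi, psi) = (-57, -47)` degrees; coil residues
#' draw `(phi, psi)` uniformly from the beta/PPII region (`phi` in
#' \[-160, -60\], `psi` in \[90, 170\]), which is disjoint from the helix
#' detection window so ground-truth helicity is unambiguous.  Deterministic
#' under `seed`.
#'
#' @param sequence character vector of 3-letter residue codes (SEP
#'   allowed).
#' @param helix logical vector (one per residue): helical vs coil.
#'   Alternatively a numeric 2-column matrix of explicit (phi, psi).
#' @param chain chain id (default "A").
#' @param resno_start first residue number (default 1).
#' @param seed RNG seed for the coil draws (NULL = use current stream).
#' @param phi_helix,psi_helix helical dihedrals, degrees.
#' @return an [idp_structure()].
#' @export
build_conformer <- function(sequence, helix = rep(FALSE, length(sequence)),
                            chain = "A", resno_start = 1L, seed = NULL,
                            phi_helix = -57, psi_helix = -47) {
  sequence <- toupper(sequence)
  bad <- setdiff(sequence, names(SIDECHAIN_ATOMS))
  if (length(bad)) stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  nres <- length(sequence)
  if (is.matrix(helix)) {
    stopifnot(nrow(helix) == nres, ncol(helix) == 2L)
    phi <- helix[, 1L]; psi <- helix[, 2L]
  } else {
    stopifnot(length(helix) == nres)
    phi <- psi <- numeric(nres)
    with_seed(seed, {
      for (i in seq_len(nres)) {
        if (helix[i]) {
          phi[i] <- phi_helix; psi[i] <- psi_helix
        } else {
          phi[i] <- stats::runif(1L, -160, -60)
          psi[i] <- stats::runif(1L, 90, 170)
        }
      }
    })
  }
  g <- .GEOM
  natom_tot <- sum(4L + lengths(SIDECHAIN_ATOMS[sequence]))
  name <- character(natom_tot); resid <- character(natom_tot)
  resno <- integer(natom_tot)
  xyz <- matrix(0, natom_tot, 3L)
  n_cur <- 0L
  add <- function(nm, rs, rn, pos) {
    n_cur <<- n_cur + 1L
    name[n_cur] <<- nm; resid[n_cur] <<- rs; resno[n_cur] <<- rn
    xyz[n_cur, ] <<- pos
  }
  prevN <- prevCA <- prevC <- NULL
  for (i in seq_len(nres)) {
    rs <- sequence[i]; rn <- resno_start + i - 1L
    if (i == 1L) {
      N <- c(0, 0, 0)
      CA <- c(g$b_n_ca, 0, 0)
      a <- (180 - g$a_n_ca_c) * pi / 180
      C <- CA + g$b_ca_c * c(cos(a), sin(a), 0)
    } else {
      N <- .place_atom(prevN, prevCA, prevC, g$b_c_n, g$a_ca_c_n, psi[i - 1L])
      CA <- .place_atom(prevCA, prevC, N, g$b_n_ca, g$a_c_n_ca, g$omega)
      C <- .place_atom(prevC, N, CA, g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    O <- .place_atom(N, CA, C, g$b_c_o, g$a_ca_c_o, psi[i] + 180)
    add("N", rs, rn, N); add("CA", rs, rn, CA); add("C", rs, rn, C)
    add("O", rs, rn, O)
    sc <- SIDECHAIN_ATOMS[[rs]]
    if (length(sc)) {
      CB <- .place_atom(C, N, CA, g$b_ca_cb, g$a_n_ca_cb, 122.55)
      add("CB", rs, rn, CB)
      extra <- setdiff(sc, "CB")
      if (length(extra)) {
        u <- .unit(CB - CA)
        v <- .unit(.cross(u, N - CA))
        w <- .cross(u, v)
        off <- .sidechain_offsets(length(extra))
        pos <- sweep(off %*% rbind(u, v, w), 2L, CB, "+")
        for (k in seq_along(extra)) add(extra[k], rs, rn, pos[k, ])
      }
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }
  atoms <- data.frame(eleno = seq_along(name), elety = name, resid = resid,
                      chain = chain, resno = resno,
                      elesy = element_from_name(name),
                      stringsAsFactors = FALSE)
  rownames(xyz) <- NULL
  idp_structure(atoms, xyz)
}
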