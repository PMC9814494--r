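# Independent brute-force oracles (plain double loops, no shared code with
# the package internals) and small fixture builders.

# all residue pairs (labels "chain:resno") whose minimum atom-atom distance
# over the given atom index sets is strictly below d_c
oracle_contact_pairs <- function(structure, idxA, idxB, d_c) {
  a <- structure$atoms
  xyz <- structure$xyz
  lab <- function(i) paste0(a$chain[i], ":", a$resno[i])
  hits <- list()
  for (i in idxA) {
    for (j in idxB) {
      if (a$chain[i] == a$chain[j] && a$resno[i] == a$resno[j]) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < d_c) {
        key <- paste(lab(i), lab(j))
        hits[[key]] <- c(lab(i), lab(j))
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(res_a = character(0), res_b = character(0)))
  }
  m <- do.call(rbind, hits)
  out <- unique(data.frame(res_a = m[, 1L], res_b = m[, 2L],
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[order(out$res_a, out$res_b), ]
}

# brute-force HRC pair count: atom pairs across different residues of the
# set, strictly below cutoff
oracle_hrc_count <- function(structure, residues, chain, d_c) {
  a <- structure$atoms
  sel <- which(a$chain == chain & a$resno %in% residues &
                 toupper(a$elesy) != "H" &
                 !a$elety %in% c("N", "CA", "C", "O", "OXT"))
  cnt <- 0L
  for (p in seq_along(sel)) {
    for (q in seq_along(sel)) {
      if (q <= p) next
      i <- sel[p]; j <- sel[q]
      if (a$resno[i] == a$resno[j]) next
      d <- sqrt(sum((structure$xyz[i, ] - structure$xyz[j, ])^2))
      if (d < d_c) cnt <- cnt + 1L
    }
  }
  cnt
}

# a tiny hand-positionable structure: each residue gets one CA (backbone)
# and `n_side` side-chain pseudo atoms at given positions
make_point_structure <- function(residue_positions, chain = "A",
                                 resid = "LEU") {
  atoms <- NULL
  xyz <- NULL
  for (k in seq_along(residue_positions)) {
    pos <- residue_positions[[k]]
    stopifnot(is.matrix(pos), ncol(pos) == 3L)
    n_side <- nrow(pos)
    nm <- c("CA", paste0("CB", seq_len(n_side) - 1L))
    nm[2L] <- "CB"
    if (n_side >= 2L) nm[3:(n_side + 1L)] <- paste0("CG", seq_len(n_side - 1L))
    ca <- pos[1L, ] + c(0, 0, 50)  # backbone far above: never in contact
    atoms <- rbind(atoms, data.frame(
      eleno = 0L, elety = nm[seq_len(n_side + 1L)], resid = resid,
      chain = chain, resno = k, elesy = "C", stringsAsFactors = FALSE))
    xyz <- rbind(xyz, ca, pos)
  }
  atoms$eleno <- seq_len(nrow(atoms))
  idp_structure(atoms, xyz)
}

# random small multi-chain structures for oracle-equivalence sweeps
random_structure <- function(n_res_a = 5L, n_res_b = 0L, spread = 8) {
  res <- function(chain, resno) {
    n_side <- sample(1:4, 1L)
    ctr <- runif(3L, -spread, spread)
    pos <- matrix(rep(ctr, each = n_side), n_side, 3L) +
      matrix(runif(3L * n_side, -2, 2), n_side, 3L)
    nm <- c("CB", if (n_side > 1L) paste0("CG", seq_len(n_side - 1L)))
    data.frame(elety = c("CA", nm), resid = "ALA", chain = chain,
               resno = resno, elesy = "C",
               x = c(ctr[1L], pos[, 1L]), y = c(ctr[2L], pos[, 2L]),
               z = c(ctr[3L], pos[, 3L]), stringsAsFactors = FALSE)
  }
  rows <- list()
  for (r in seq_len(n_res_a)) rows[[length(rows) + 1L]] <- res("A", r)
  for (r in seq_len(n_res_b)) rows[[length(rows) + 1L]] <- res("B", r)
  df <- do.call(rbind, rows)
  df$eleno <- seq_len(nrow(df))
  idp_structure(df[, c("eleno", "elety", "resid", "chain", "resno", "elesy")],
                as.matrix(df[, c("x", "y", "z")]))
}

# random rigid motion applied to a structure
random_rigid_motion <- function(s) {
  th <- runif(3L, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1])), 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0, sin(th[2]), 0, cos(th[2])), 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3)
  s$xyz <- s$xyz %*% (Rx %*% Ry %*% Rz) +
    matrix(runif(3L, -30, 30), nrow(s$xyz), 3L, byrow = TRUE)
  s
}

# canonical sorted "a|b" key set for pair data frames
pair_keys <- function(df) sort(paste(df$res_a, df$res_b))

# default demo fixtures shared across tests
demo_interface <- function() synthetic_interface()

demo_reference <- function() {
  generate_reference_complex(synthetic_pkid_sequence(),
                             synthetic_kix_sequence(),
                             demo_interface())
}
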