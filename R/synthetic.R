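# Seeded synthetic ensembles with exact ground truth.
#
# The generators impose structure geometrically (dihedral assignment,
# centroid compaction of hydrophobic side chains, rigid placement of a
# peptide against its partner) -- no physics.  Analysis code must not care
# how conformations arose, so every generator parameter is recoverable by
# the corresponding analysis operation.

#' Synthetic pKID-like peptide sequence
#'
#' A designed 29-residue stand-in for a phosphorylated kinase-inducible
#' domain, numbered 119-147: phosphoserine at 133, the hydrophobic-cluster
#' residues Leu128 / Tyr134 / Ile137 / Leu138 (plus Leu141), and the
#' flanking positively charged residues.  It is *not* the natural CREB
#' sequence; it exists so the analysis stack can be exercised without any
#' deposited data.
#'
#' @param phospho if `FALSE`, residue 133 is SER instead of SEP (the
#'   unphosphorylated variant).
#' @return named character vector (names = residue numbers 119..147).
#' @export
synthetic_pkid_sequence <- function(phospho = TRUE) {
  seqs <- c("SER", "GLN", "LEU", "ALA", "GLU", "ARG", "ARG", "ALA", "SER",
            "LEU", "GLN", "ARG", "ARG", "SER",
            if (phospho) "SEP" else "SER",
            "TYR", "ARG", "LYS", "ILE", "LEU", "ASN", "ASP", "LEU", "SER",
            "SER", "ASP", "ALA", "GLN", "GLY")
  names(seqs) <- 119:147
  seqs
}

#' Synthetic KIX-like partner sequence
#'
#' A designed 40-residue folded-partner stand-in, numbered 601-640, with
#' hydrophobic and charged positions but no long aromatic side chains (the
#' generator keeps the two chains' side-chain envelopes from touching
#' except at designed interface contacts).
#'
#' @return named character vector (names = residue numbers 601..640).
#' @export
synthetic_kix_sequence <- function() {
  seqs <- rep(c("ALA", "GLU", "LEU", "LYS", "VAL", "SER", "ILE", "GLN",
                "LEU", "ASP"), 4L)
  names(seqs) <- 601:640
  seqs
}

#' Default designed interface for the synthetic complex
#'
#' Twelve residue pairs between the synthetic pKID-like chain and the
#' synthetic KIX-like partner, chosen with matching axial positions on the
#' two parallel helices (each pair is geometrically realisable) and
#' including the hydrophobic-cluster residues 134/137/138.
#'
#' @return data frame with columns `idp` and `partner` (residue numbers).
#' @export
synthetic_interface <- function() {
  data.frame(
    idp     = c(121L, 124L, 125L, 128L, 131L, 132L, 134L, 136L, 137L, 138L,
                141L, 143L),
    partner = c(609L, 611L, 613L, 615L, 618L, 620L, 621L, 623L, 624L, 625L,
                628L, 631L)
  )
}

# decompose a per-residue probability profile into maximal constant runs;
# each run is an all-or-none cooperative helix unit
.profile_runs <- function(profile, min_run = 4L) {
  r <- rle(profile)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  short <- r$values > 0 & r$lengths < min_run
  if (any(short)) {
    warning("helicity profile has runs shorter than min_run (", min_run,
            "); the dihedral rule cannot detect them")
  }
  data.frame(start = starts, end = ends, p = r$values)
}

# scale the HRC residues' side-chain atoms about their joint centroid until
# the contact-count condition holds.  An HRC frame is a *spatial* cluster:
# compaction continues until, besides the count threshold, every residue
# pair of the set is in mutual side-chain contact (adjacent residues alone
# can clear the count threshold without any cluster forming).
.force_hrc_state <- function(s, spec, target, max_iter = 200L) {
  idx_by_res <- .hrc_atoms(s, spec)
  idx <- unlist(idx_by_res)
  all_touch <- function(s) {
    for (a in seq_along(idx_by_res)) {
      for (b in seq_along(idx_by_res)) {
        if (b <= a) next
        d2 <- .pair_dist2(s$xyz[idx_by_res[[a]], , drop = FALSE],
                          s$xyz[idx_by_res[[b]], , drop = FALSE])
        if (min(d2) >= spec$cutoff^2) return(FALSE)
      }
    }
    TRUE
  }
  for (it in seq_len(max_iter)) {
    cnt <- hrc_contact_count(s, spec)
    if (isTRUE(target) && cnt > spec$threshold && all_touch(s)) return(s)
    if (!isTRUE(target) && cnt <= spec$threshold) return(s)
    ctr <- colMeans(s$xyz[idx, , drop = FALSE])
    fac <- if (target) 0.85 else 1.3
    s$xyz[idx, ] <- sweep(fac * sweep(s$xyz[idx, , drop = FALSE], 2L, ctr),
                          2L, ctr, "+")
  }
  stop("HRC compaction did not converge")
}

#' Generate a free-state synthetic ensemble with known ground truth
#'
#' Per frame, each maximal constant-probability run of the helicity profile
#' is helical all-or-none with its probability (cooperative units of
#' length >= `min_run`, so the dihedral rule detects exactly the residues
#' that were set); with probability `p_hrc` the frame's hydrophobic-cluster
#' side chains are pulled toward their joint centroid until the contact
#' count exceeds the threshold, and otherwise pushed apart until it does
#' not, so the per-frame HRC flag is exact.
#'
#' @param sequence named character vector of 3-letter codes (names =
#'   residue numbers), e.g. [synthetic_pkid_sequence()].
#' @param helix_profile numeric vector in \[0, 1\], one per residue: target
#'   per-residue helicity.
#' @param n_frames number of frames (>= 1).
#' @param seed RNG seed (required for reproducibility).
#' @param p_hrc target HRC formation probability in \[0, 1\].
#' @param hrc an [hrc_spec()] (ignored when `p_hrc` is `NULL`).
#' @param chain chain id.
#' @param min_run cooperative-unit length the dihedral rule can detect.
#' @return list with `ensemble` (an [idp_ensemble()], uniform weights) and
#'   `truth` (list: `helix` n_frames x n_residues logical matrix, `hrc`
#'   logical vector, `helix_profile`, `p_hrc`).
#' @export
generate_free_ensemble <- function(sequence, helix_profile, n_frames, seed,
                                   p_hrc = NULL, hrc = hrc_spec(),
                                   chain = "A", min_run = 4L) {
  stopifnot(length(helix_profile) == length(sequence),
            all(helix_profile >= 0 & helix_profile <= 1),
            n_frames >= 1L)
  if (!is.null(p_hrc)) stopifnot(p_hrc >= 0, p_hrc <= 1)
  resno_start <- suppressWarnings(as.integer(names(sequence)[1L]))
  if (is.na(resno_start) || !length(resno_start)) resno_start <- 1L
  runs <- .profile_runs(helix_profile, min_run)
  with_seed(seed, {
    helix_mat <- matrix(FALSE, n_frames, length(sequence))
    for (k in seq_len(nrow(runs))) {
      if (runs$p[k] <= 0) next
      on <- stats::runif(n_frames) < runs$p[k]
      helix_mat[on, runs$start[k]:runs$end[k]] <- TRUE
    }
    hrc_flag <- if (is.null(p_hrc)) rep(NA, n_frames) else stats::runif(n_frames) < p_hrc
    frames <- vector("list", n_frames)
    atoms <- NULL
    for (f in seq_len(n_frames)) {
      s <- build_conformer(sequence, helix_mat[f, ], chain = chain,
                           resno_start = resno_start)
      if (!is.null(p_hrc)) {
        spec <- hrc
        if (is.null(spec$chain)) spec$chain <- chain
        s <- .force_hrc_state(s, spec, target = hrc_flag[f])
      }
      frames[[f]] <- s$xyz
      if (is.null(atoms)) atoms <- s$atoms
    }
    ens <- idp_ensemble(atoms, frames)
    list(ensemble = ens,
         truth = list(helix = helix_mat, hrc = hrc_flag,
                      helix_profile = helix_profile, p_hrc = p_hrc))
  })
}

# Align a helical chain: principal CA axis to z, CA centroid to origin.
.align_chain <- function(s) {
  idx <- select_atoms(s, "alpha-carbon", warn_empty = FALSE)
  ax <- helix_axis(s, range(s$atoms$resno))
  R <- .rotation_between(ax, c(0, 0, 1))
  ctr <- colMeans(s$xyz[idx, , drop = FALSE])
  s$xyz <- sweep(s$xyz, 2L, ctr) %*% t(R)
  s
}

# rotate a z-aligned chain about z so the given residues' side chains face
# the +x (face = +1) or -x (face = -1) half-space on average
.face_residues <- function(s, residues, face = +1) {
  idx <- select_atoms(s, atom_selection(residues = residues,
                                        atoms = "side-chain-heavy"),
                      warn_empty = FALSE)
  if (!length(idx)) return(s)
  xy <- s$xyz[idx, 1:2, drop = FALSE]
  ang <- atan2(mean(xy[, 2L]), mean(xy[, 1L]))
  tgt <- if (face > 0) 0 else pi
  s$xyz <- s$xyz %*% t(.rot_z(tgt - ang))
  s
}

#' Generate a synthetic reference bound complex
#'
#' Builds both chains as ideal helices, aligns their axes in parallel at
#' `offset` angstrom, and pulls the IDP-side side chain of every designed
#' interface pair radially onto its partner residue (3-A standoff), so each
#' designed pair satisfies the contact rule while no undesigned pair does.
#'
#' @param idp_sequence,partner_sequence named 3-letter-code vectors (names
#'   = residue numbers).
#' @param interface data frame with columns `idp` and `partner` (residue
#'   numbers): the designed native contacts.
#' @param chain_idp,chain_partner chain ids (default "A", "B").
#' @param offset axis-to-axis distance in angstrom (default 18; large
#'   enough that undesigned side chains cannot touch).
#' @param standoff designed-contact distance in angstrom (default 3).
#' @param seed RNG seed (the bound conformers are deterministic; the seed
#'   covers nothing today but is kept in the contract).
#' @return an [idp_structure()] with both chains; attribute `interface`
#'   echoes the designed pairs as "chain:resno" labels.
#' @export
generate_reference_complex <- function(idp_sequence, partner_sequence,
                                       interface,
                                       chain_idp = "A", chain_partner = "B",
                                       offset = 18, standoff = 3,
                                       seed = NULL) {
  stopifnot(is.data.frame(interface), nrow(interface) >= 1L,
            all(c("idp", "partner") %in% names(interface)))
  idp <- build_conformer(idp_sequence, rep(TRUE, length(idp_sequence)),
                         chain = chain_idp,
                         resno_start = as.integer(names(idp_sequence)[1L]))
  par <- build_conformer(partner_sequence, rep(TRUE, length(partner_sequence)),
                         chain = chain_partner,
                         resno_start = as.integer(names(partner_sequence)[1L]))
  idp <- .face_residues(.align_chain(idp), interface$idp, face = -1)
  par <- .face_residues(.align_chain(par), interface$partner, face = +1)

  # axial registration: designed pairs meet at matching z
  zi <- vapply(interface$idp, function(r) {
    mean(idp$xyz[select_atoms(idp, atom_selection(residues = r, atoms = "alpha-carbon"),
                              warn_empty = FALSE), 3L])
  }, numeric(1L))
  zp <- vapply(interface$partner, function(r) {
    mean(par$xyz[select_atoms(par, atom_selection(residues = r, atoms = "alpha-carbon"),
                              warn_empty = FALSE), 3L])
  }, numeric(1L))
  idp$xyz[, 3L] <- idp$xyz[, 3L] + mean(zp) - mean(zi)
  idp$xyz[, 1L] <- idp$xyz[, 1L] + offset

  cplx <- idp_structure(rbind(par$atoms, idp$atoms), rbind(par$xyz, idp$xyz))
  cplx$atoms$eleno <- seq_len(nrow(cplx$atoms))
  unpulled_xyz <- cplx$xyz
  cplx <- .pull_pairs(cplx, interface, chain_idp, chain_partner, standoff)

  ncs <- native_contacts_from_reference(cplx, chain_idp, chain_partner)
  designed <- paste0(chain_idp, ":", interface$idp, " ",
                     chain_partner, ":", interface$partner)
  got <- paste(ncs$res_a, ncs$res_b)
  if (!setequal(got, designed)) {
    stop("reference-complex placement failed: designed and realised native ",
         "contacts differ (extra: ",
         paste(setdiff(got, designed), collapse = "; "), "; missing: ",
         paste(setdiff(designed, got), collapse = "; "), ")")
  }
  attr(cplx, "interface") <- data.frame(res_a = paste0(chain_idp, ":", interface$idp),
                                        res_b = paste0(chain_partner, ":", interface$partner),
                                        stringsAsFactors = FALSE)
  # the pre-pull geometry: no inter-chain contacts anywhere; ensemble
  # generation starts frames from this and re-forms chosen contacts only
  attr(cplx, "unpulled_xyz") <- unpulled_xyz
  cplx
}

# pull the IDP side chain of each interface pair onto its partner residue
# (radially outward standoff from the partner's tip atom); max_stretch
# bounds the translation so unreachable pulls error out
.pull_pairs <- function(cplx, interface, chain_idp, chain_partner, standoff,
                        max_stretch = 30) {
  for (k in seq_len(nrow(interface))) {
    tip <- .tip_atom_chain(cplx, chain_partner, interface$partner[k])
    tippos <- cplx$xyz[tip, ]
    u_out <- .unit(c(tippos[1L], tippos[2L], 0))
    target <- tippos + standoff * u_out
    grp <- select_atoms(cplx, atom_selection(chains = chain_idp,
                                             residues = interface$idp[k],
                                             atoms = "side-chain-heavy"),
                        warn_empty = FALSE)
    if (!length(grp)) {
      stop("interface residue ", chain_idp, ":", interface$idp[k],
           " has no side-chain heavy atoms")
    }
    d2 <- rowSums(sweep(cplx$xyz[grp, , drop = FALSE], 2L, target)^2)
    stretch <- sqrt(min(d2))
    if (stretch > max_stretch) {
      stop("designed contact ", chain_idp, ":", interface$idp[k], "-",
           chain_partner, ":", interface$partner[k],
           " is unreachable (required stretch ",
           sprintf("%.1f", stretch), " A > ", max_stretch, " A)")
    }
    # re-form the contact: the side chain collapses onto a compact cluster
    # whose innermost atom sits at the standoff point, extending radially
    # outward so no undesigned partner residue is approached
    v <- .unit(.cross(c(0, 0, 1), u_out))
    j <- seq_along(grp) - 1L
    off <- cbind(0.3 * j, 0.5 * cos(2.1 * j), 0.5 * sin(2.1 * j))
    cplx$xyz[grp, ] <- sweep(off %*% rbind(u_out, v, c(0, 0, 1)), 2L,
                             target, "+")
  }
  cplx
}

.tip_atom_chain <- function(s, chain, resno) {
  idx <- select_atoms(s, atom_selection(chains = chain, residues = resno,
                                        atoms = "side-chain-heavy"),
                      warn_empty = FALSE)
  if (!length(idx)) stop("residue ", chain, ":", resno, " has no side-chain heavy atoms")
  r2 <- rowSums(s$xyz[idx, 1:2, drop = FALSE]^2)
  idx[which.max(r2)]
}

#' Mixture specification for a synthetic complex ensemble
#'
#' @param name state names (e.g. "F", "B").
#' @param fraction mixture fractions (must sum to 1).
#' @param d_mean,d_sd target centre-of-mass distance distribution per
#'   state (angstrom).
#' @param q_mean,q_sd target fraction-of-native-contacts distribution per
#'   state (clamped to \[0, 1\]).
#' @return data frame of class `state_mixture`.
#' @export
state_mixture <- function(name, fraction, d_mean, d_sd, q_mean, q_sd) {
  out <- data.frame(name = name, fraction = fraction, d_mean = d_mean,
                    d_sd = d_sd, q_mean = q_mean, q_sd = q_sd,
                    stringsAsFactors = FALSE)
  if (abs(sum(out$fraction) - 1) > 1e-8) stop("state fractions must sum to 1")
  if (any(out$fraction < 0)) stop("state fractions must be >= 0")
  class(out) <- c("state_mixture", "data.frame")
  out
}

#' Generate a synthetic complex ensemble with known per-frame states
#'
#' Per frame a state is drawn from the mixture; the IDP chain is rigidly
#' translated along the chain-chain axis so the (pre-pull) centre-of-mass
#' distance equals the state's draw, and a random subset of the designed
#' native contacts of size `round(q_draw * K)` is re-formed by the same
#' radial side-chain pull used for the reference.  Unreachable
#' (distance, Q) combinations error out at validation.
#'
#' @param reference a [generate_reference_complex()] result (carries the
#'   designed interface).
#' @param mixture a [state_mixture()].
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param chain_idp,chain_partner chain ids as in the reference.
#' @param max_stretch maximum side-chain pull in angstrom (default 30;
#'   pulls start from the unpulled side-chain position, so the bound at the
#'   reference distance is generous while far-separated high-Q states still
#'   error out).
#' @return list with `ensemble` and `truth` (data frame: `frame`, `state`,
#'   `d_target`, `q_target`, `n_target`).
#' @export
generate_complex_ensemble <- function(reference, mixture, n_frames, seed,
                                      chain_idp = "A", chain_partner = "B",
                                      max_stretch = 30) {
  interface <- attr(reference, "interface")
  if (is.null(interface)) stop("reference lacks a designed interface attribute")
  K <- nrow(interface)
  iface_num <- data.frame(idp = as.integer(sub(".*:", "", interface$res_a)),
                          partner = as.integer(sub(".*:", "", interface$res_b)))
  selA <- atom_selection(chains = chain_idp, atoms = "all-heavy")
  selB <- atom_selection(chains = chain_partner, atoms = "all-heavy")

  # frames start from the pre-pull geometry (no inter-chain contacts) and
  # re-form only the chosen subset of designed contacts
  base <- reference
  if (is.null(attr(reference, "unpulled_xyz"))) {
    stop("reference lacks the pre-pull geometry attribute")
  }
  base$xyz <- attr(reference, "unpulled_xyz")
  d_ref <- com_distance(base, selA, selB)
  idp_idx <- which(base$atoms$chain == chain_idp)

  # reachability validation: trial-place each contact-forming state at its
  # upper working distance (mean + 2 sd) and pull every designed pair
  for (st in seq_len(nrow(mixture))) {
    if (mixture$q_mean[st] * K < 0.5 || mixture$fraction[st] <= 0) next
    d_hi <- mixture$d_mean[st] + 2 * mixture$d_sd[st]
    trial <- base
    comA <- .sel_com(trial, selA); comB <- .sel_com(trial, selB)
    v <- comA - comB
    trial$xyz[idp_idx, ] <- sweep(trial$xyz[idp_idx, , drop = FALSE], 2L,
                                  v * (max(d_hi, d_ref) / sqrt(sum(v^2)) - 1), "+")
    ok <- tryCatch({
      .pull_pairs(trial, iface_num, chain_idp, chain_partner, standoff = 3,
                  max_stretch = max_stretch)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      stop("unreachable (d_com, Q) combination for state ", mixture$name[st],
           " (d ~ ", d_hi, " A with q_mean ", mixture$q_mean[st], ")")
    }
  }

  with_seed(seed, {
    states <- sample(seq_len(nrow(mixture)), n_frames, replace = TRUE,
                     prob = mixture$fraction)
    frames <- vector("list", n_frames)
    truth <- data.frame(frame = seq_len(n_frames),
                        state = mixture$name[states],
                        d_target = NA_real_, q_target = NA_real_,
                        n_target = NA_integer_)
    for (f in seq_len(n_frames)) {
      st <- states[f]
      d <- stats::rnorm(1L, mixture$d_mean[st], mixture$d_sd[st])
      d <- min(max(d, d_ref), mixture$d_mean[st] + 2 * mixture$d_sd[st])
      q <- min(max(stats::rnorm(1L, mixture$q_mean[st], mixture$q_sd[st]), 0), 1)
      n_tgt <- as.integer(round(q * K))
      s <- base
      # rigid translation of the IDP chain along the chain-chain COM axis
      comA <- .sel_com(s, selA); comB <- .sel_com(s, selB)
      v <- comA - comB
      s$xyz[idp_idx, ] <- sweep(s$xyz[idp_idx, , drop = FALSE], 2L,
                                v * (d / sqrt(sum(v^2)) - 1), "+")
      if (n_tgt > 0L) {
        chosen <- sample(K, n_tgt)
        s <- .pull_pairs(s, iface_num[chosen, , drop = FALSE],
                         chain_idp, chain_partner, standoff = 3,
                         max_stretch = max_stretch)
      }
      truth$d_target[f] <- d
      truth$q_target[f] <- n_tgt / K
      truth$n_target[f] <- n_tgt
      frames[[f]] <- s$xyz
    }
    ens <- idp_ensemble(base$atoms, frames)
    list(ensemble = ens, truth = truth)
  })
}

.sel_com <- function(s, sel) {
  idx <- select_atoms(s, sel, warn_empty = FALSE)
  m <- mass_of_elements(s$atoms$elesy[idx])
  colSums(s$xyz[idx, , drop = FALSE] * m) / sum(m)
}

#' Generate a seeded random cluster table
#'
#' Feeds the Boltzmann-reweighted observable average with controllable
#' ground truth.
#'
#' @param n_clusters number of clusters (>= 1).
#' @param f_range range (kJ/mol) for uniform free-energy draws.
#' @param o_rule `"constant"` (all `o_value`), `"linear"` (`O = o_value *
#'   F`), or `"random"` (uniform on \[0, 1\]).
#' @param o_value constant value or linear coefficient.
#' @param seed RNG seed.
#' @param temperature Kelvin.
#' @return a [cluster_table()].
#' @export
generate_cluster_table <- function(n_clusters, f_range = c(0, 20),
                                   o_rule = c("constant", "linear", "random"),
                                   o_value = 1, seed = NULL,
                                   temperature = 300) {
  o_rule <- match.arg(o_rule)
  stopifnot(n_clusters >= 1L)
  with_seed(seed, {
    f <- stats::runif(n_clusters, f_range[1L], f_range[2L])
    o <- switch(o_rule,
                constant = rep(o_value, n_clusters),
                linear = o_value * f,
                random = stats::runif(n_clusters))
    cluster_table(seq_len(n_clusters), f, o, temperature = temperature)
  })
}
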