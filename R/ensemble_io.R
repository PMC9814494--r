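# Ensemble I/O: multi-model PDB (via bio3d) plus the plain-text side tables
# (per-frame weights, per-cluster free energies, chemical-shift tables).
#
# bio3d does the PDB parsing and writing; this layer adds the ensemble
# contract: per-model topology validation (every MODEL must contain the
# same atoms in the same order), coordinate-field checks with line numbers,
# and alternate-location filtering (keep altloc 'A' or blank).

.is_atom_line <- function(lines) grepl("^(ATOM  |HETATM)", lines)

.atom_line_label <- function(lines) {
  paste0(trimws(substr(lines, 13, 16)), "/",
         trimws(substr(lines, 18, 20)), "/",
         substr(lines, 22, 22), "/",
         trimws(substr(lines, 23, 26)))
}

.keep_altloc <- function(lines) substr(lines, 17, 17) %in% c(" ", "", "A")

#' Read a multi-model PDB file as a conformational ensemble
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records is read as a one-frame ensemble.  All models must share one
#' topology (same atoms, same order); residue numbers are taken verbatim
#' from the file.  Alternate locations other than `'A'`/blank are dropped.
#' Hydrogens are kept (selections exclude them later by element).
#'
#' @param path PDB file path.
#' @return an [idp_ensemble()] with uniform weights.
#' @seealso [write_pdb_ensemble()], [read_weights()]
#' @export
read_pdb_ensemble <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  is_atom <- .is_atom_line(lines)

  # coordinate-field validation with line numbers
  atom_lnos <- which(is_atom)
  for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
    v <- suppressWarnings(as.numeric(substr(lines[atom_lnos], fld[1], fld[2])))
    if (anyNA(v)) {
      stop("unparseable coordinate field at line ", atom_lnos[which(is.na(v))[1L]])
    }
  }

  # per-model topology validation
  if (length(model_starts) >= 1L) {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts)) {
      stop("unbalanced MODEL/ENDMDL records")
    }
    blocks <- lapply(seq_along(model_starts), function(k) {
      blk <- lines[model_starts[k]:model_ends[k]]
      blk <- blk[.is_atom_line(blk)]
      blk[.keep_altloc(blk)]
    })
  } else {
    blocks <- list(lines[is_atom & .keep_altloc(lines)])
  }
  if (length(blocks[[1L]]) == 0L) stop("no ATOM/HETATM records in ", path)
  ref_lab <- .atom_line_label(blocks[[1L]])
  for (k in seq_along(blocks)[-1L]) {
    lab <- .atom_line_label(blocks[[k]])
    if (length(lab) != length(ref_lab)) {
      n <- min(length(lab), length(ref_lab))
      div <- if (n == 0L) 1L else {
        d <- which(lab[seq_len(n)] != ref_lab[seq_len(n)])
        if (length(d)) d[1L] else n + 1L
      }
      stop("topology mismatch: model ", k, " has ", length(lab),
           " atoms (model 1 has ", length(ref_lab), "); first divergence at atom ",
           div, " (", if (div <= length(ref_lab)) ref_lab[div] else "<absent>", ")")
    }
    if (any(lab != ref_lab)) {
      div <- which(lab != ref_lab)[1L]
      stop("topology mismatch: model ", k, ", atom ", div,
           ": expected ", ref_lab[div], ", found ", lab[div])
    }
  }

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  a <- pdb$atom
  keep <- is.na(a$alt) | a$alt %in% c("", " ", "A")
  cols <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1, 3 * which(keep)))
  xyz <- pdb$xyz[, cols, drop = FALSE]
  a <- a[keep, , drop = FALSE]
  chain <- ifelse(is.na(a$chain), " ", a$chain)
  atoms <- data.frame(eleno = a$eleno, elety = a$elety, resid = a$resid,
                      chain = chain, resno = a$resno, elesy = a$elesy,
                      stringsAsFactors = FALSE)
  idp_ensemble(atoms, xyz)
}

#' Read a single-model PDB file as a structure
#'
#' Convenience wrapper used for reference bound complexes; errors if the
#' file holds more than one model.
#'
#' @param path PDB file path.
#' @return an [idp_structure()].
#' @export
read_pdb_structure <- function(path) {
  e <- read_pdb_ensemble(path)
  if (n_frames(e) != 1L) {
    stop("expected a single-model reference PDB, found ", n_frames(e), " models")
  }
  get_frame(e, 1L)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are written at the PDB's 3-decimal precision, so
#' `read_pdb_ensemble(write_pdb_ensemble(e))` reproduces `e` to 1e-3 A.
#' Per-frame weights are not stored in the PDB; keep them in a side table
#' (see [read_weights()]).
#'
#' @param ensemble an [idp_ensemble()] or [idp_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  if (inherits(ensemble, "idp_structure")) {
    ensemble <- idp_ensemble(ensemble$atoms, list(ensemble$xyz))
  }
  stopifnot(inherits(ensemble, "idp_ensemble"))
  a <- ensemble$atoms
  tryCatch({
    bio3d::write.pdb(file = path, xyz = ensemble$xyz,
                     resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$elety,
                     chain = a$chain, elesy = a$elesy)
  }, error = function(e) {
    stop("cannot write PDB to ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  if (nrow(ensemble$xyz) == 1L) {
    # bio3d omits MODEL wrappers for a single frame; keep the multi-model
    # container even then
    lines <- readLines(path, warn = FALSE)
    first <- which(.is_atom_line(lines))[1L]
    lines <- append(lines, "MODEL        1", after = first - 1L)
    lines <- append(lines, "ENDMDL", after = max(which(.is_atom_line(lines))))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read per-frame statistical weights
#'
#' Plain tabular text (comma- or whitespace-separated, `#` comments), two
#' columns: frame index (1-based) and weight.  Every frame of the ensemble
#' must appear exactly once.  Weights are returned as given -- no
#' normalisation -- since all downstream statistics are invariant under
#' uniform rescaling.
#'
#' @param path file path.
#' @param n_frames expected number of frames.
#' @return numeric vector of length `n_frames`, ordered by frame index.
#' @export
read_weights <- function(path, n_frames) {
  tab <- .read_side_table(path, "weights")
  if (ncol(tab) < 2L) stop("weights table needs two columns (frame, weight)")
  frame <- as.integer(tab[[1L]])
  w <- as.numeric(tab[[2L]])
  if (anyNA(frame) || anyNA(w)) stop("non-numeric entries in weights table ", path)
  if (anyDuplicated(frame)) stop("duplicate frame index in weights table ", path)
  missing <- setdiff(seq_len(n_frames), frame)
  if (length(missing) || length(frame) != n_frames) {
    stop("weights table ", path, " does not cover frames 1..", n_frames,
         if (length(missing)) paste0(" (missing: ",
                                     paste(utils::head(missing, 5L), collapse = ", "), ")"))
  }
  if (any(w < 0)) stop("negative weight at frame ", frame[which(w < 0)[1L]])
  if (sum(w) <= 0) stop("all weights are zero")
  w[order(frame)]
}

# comma- or whitespace-separated, '#' comments; returns a data.frame
.read_side_table <- function(path, what) {
  if (!file.exists(path)) stop("no such ", what, " file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty ", what, " table: ", path)
  lines <- gsub(",", " ", lines, fixed = TRUE)
  con <- textConnection(lines)
  on.exit(close(con))
  utils::read.table(con, header = FALSE, stringsAsFactors = FALSE,
                    strip.white = TRUE, comment.char = "")
}

#' Construct a per-cluster free-energy table
#'
#' Holds the cluster free energies \eqn{F_\alpha} (kJ/mol) and cluster-mean
#' observables \eqn{O_\alpha} feeding the Boltzmann-weighted ensemble
#' average (see [reweighted_observable()]), together with the temperature.
#'
#' @param cluster_id integer cluster ids (unique).
#' @param f_alpha cluster free energies, kJ/mol (finite).
#' @param o_alpha cluster-mean observable values.
#' @param temperature system temperature in Kelvin (> 0).
#' @return object of class `cluster_table` (a data frame with a
#'   `temperature` attribute).
#' @export
cluster_table <- function(cluster_id, f_alpha, o_alpha, temperature = 300) {
  cluster_id <- as.integer(cluster_id)
  f_alpha <- as.numeric(f_alpha)
  o_alpha <- as.numeric(o_alpha)
  if (length(cluster_id) < 1L) stop("cluster table must have at least one row")
  if (anyDuplicated(cluster_id)) stop("duplicate cluster_id")
  if (any(!is.finite(f_alpha))) stop("F_alpha must be finite")
  if (!is.finite(temperature) || temperature <= 0) stop("temperature must be > 0")
  out <- data.frame(cluster_id = cluster_id, f_alpha = f_alpha,
                    o_alpha = o_alpha)
  attr(out, "temperature") <- temperature
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Read a per-cluster free-energy table
#'
#' Three columns: cluster id, free energy \eqn{F_\alpha} (kJ/mol),
#' observable \eqn{O_\alpha}.  Comma- or whitespace-separated, `#` comments.
#'
#' @param path file path.
#' @param temperature temperature in Kelvin attached to the table.
#' @return a [cluster_table()].
#' @export
read_cluster_table <- function(path, temperature = 300) {
  tab <- .read_side_table(path, "cluster")
  if (ncol(tab) < 3L) stop("cluster table needs columns (id, F_alpha, O_alpha)")
  cluster_table(tab[[1L]], tab[[2L]], tab[[3L]], temperature = temperature)
}

#' Read a chemical-shift table
#'
#' Three columns: residue number, nucleus label (e.g. `CA`, `HA`), shift in
#' ppm.  `(residue, nucleus)` must be unique and shifts finite.
#'
#' @param path file path.
#' @return data frame with columns `residue`, `nucleus`, `shift`.
#' @export
read_shift_table <- function(path) {
  tab <- .read_side_table(path, "chemical-shift")
  if (ncol(tab) < 3L) stop("shift table needs columns (residue, nucleus, shift)")
  out <- data.frame(residue = as.integer(tab[[1L]]),
                    nucleus = toupper(as.character(tab[[2L]])),
                    shift = as.numeric(tab[[3L]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$residue) || anyNA(out$shift)) stop("non-numeric entries in ", path)
  if (any(!is.finite(out$shift))) stop("non-finite shift values in ", path)
  if (anyDuplicated(paste(out$residue, out$nucleus))) {
    stop("duplicate (residue, nucleus) rows in ", path)
  }
  out
}
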