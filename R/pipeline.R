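# Config-driven orchestration: synthesise ensembles, compute contact maps,
# and run the full ensemble-to-landscape analysis with deterministic
# outputs (CSV numbers fixed at 6 significant digits).

.log_levels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

.log <- function(config, level, ...) {
  lv <- .log_levels[[level]]
  th <- .log_levels[[config$log_level %||% "info"]]
  if (lv >= th) message("[", level, "] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("idpfel_config_error", "error")))
}

#' Read and validate a pipeline configuration
#'
#' YAML with the blocks `seed`, `temperature`, `contact_cutoff`, `chains`
#' (`idp`, `partner`), `regions` (name: \[start, end\]), `hrc`
#' (`residues`, `threshold`, `mode`), `fel` (`axis1`, `axis2`,
#' `energy_cap`, `merge_barrier`), `synth` (`free`, `complex`) and
#' optionally `inputs` (paths to an ensemble, weights, reference).  Missing
#' entries fall back to package defaults; referenced input files must
#' exist.
#'
#' @param path YAML config file.
#' @return validated config list (class `idpfel_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error("no such config file: ", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) config_error("cannot parse config: ",
                                                   conditionMessage(e)))
  cfg$seed <- cfg$seed %||% 1L
  cfg$temperature <- cfg$temperature %||% 300
  cfg$contact_cutoff <- cfg$contact_cutoff %||% 4.5
  cfg$log_level <- cfg$log_level %||% "info"
  cfg$chains <- cfg$chains %||% list(idp = "A", partner = "B")
  cfg$regions <- cfg$regions %||% list(alpha_A = c(120L, 129L),
                                       alpha_B = c(134L, 144L))
  hrc <- cfg$hrc %||% list()
  cfg$hrc_spec <- hrc_spec(
    residues = unlist(hrc$residues) %||% c(128L, 134L, 137L, 138L),
    chain = cfg$chains$idp,
    cutoff = hrc$cutoff %||% cfg$contact_cutoff,
    threshold = hrc$threshold %||% 15L,
    mode = hrc$mode %||% "pairs"
  )
  if (!is.numeric(cfg$temperature) || cfg$temperature <= 0) {
    config_error("temperature must be > 0")
  }
  if (!is.numeric(cfg$contact_cutoff) || cfg$contact_cutoff <= 0) {
    config_error("contact_cutoff must be > 0")
  }
  if (!cfg$log_level %in% names(.log_levels)) {
    config_error("log_level must be one of ",
                 paste(names(.log_levels), collapse = ", "))
  }
  for (p in unlist(cfg$inputs)) {
    if (!file.exists(p)) config_error("input file does not exist: ", p)
  }
  class(cfg) <- c("idpfel_config", "list")
  cfg
}

.fel_axes_from_config <- function(cfg) {
  fl <- cfg$fel %||% list()
  a1 <- fl$axis1 %||% list(name = "d_com", min = 10, max = 50, width = 1)
  a2 <- fl$axis2 %||% list(name = "n_native", min = -0.5, max = 13.5, width = 1)
  list(axis1 = fel_axis(a1$name, a1$min, a1$max, a1$width),
       axis2 = fel_axis(a2$name, a2$min, a2$max, a2$width),
       energy_cap = fl$energy_cap %||% 20,
       merge_barrier = fl$merge_barrier %||% 3)
}

# numeric-stable CSV writer: all double columns at 6 significant digits
write_csv_fixed <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- fmt_num(df[[j]])
  }
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.profile_from_segments <- function(segments, resno) {
  p <- rep(0, length(resno))
  for (sg in segments) {
    p[resno >= sg$from & resno <= sg$to] <- sg$p
  }
  p
}

#' Generate the synthetic demo data set of a config
#'
#' Writes the free-state ensemble (with its ground truth), the reference
#' bound complex, and the complex ensemble (with per-frame state truth) as
#' multi-model PDB plus CSV tables under `out_dir`.
#'
#' @param config an [read_run_config()] result (or path to one).
#' @param out_dir output directory (created if needed).
#' @return named character vector of written files, invisibly.
#' @export
pipeline_synth <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sy <- cfg$synth %||% list()
  seqA <- synthetic_pkid_sequence()
  seqB <- synthetic_kix_sequence()
  resno <- as.integer(names(seqA))
  out <- character(0)

  fr <- sy$free %||% list()
  segs <- fr$helix_profile %||% list(list(from = 120, to = 129, p = 0.5),
                                     list(from = 134, to = 144, p = 0.15))
  prof <- .profile_from_segments(segs, resno)
  .log(cfg, "info", "generating free ensemble (", fr$n_frames %||% 300L,
       " frames)")
  g <- generate_free_ensemble(seqA, prof, n_frames = fr$n_frames %||% 300L,
                              seed = cfg$seed, p_hrc = fr$p_hrc %||% 0.4,
                              hrc = cfg$hrc_spec)
  f_pdb <- file.path(out_dir, "free_ensemble.pdb")
  write_pdb_ensemble(g$ensemble, f_pdb)
  f_truth <- file.path(out_dir, "free_truth.csv")
  write_csv_fixed(data.frame(frame = seq_len(n_frames(g$ensemble)),
                             hrc = as.integer(g$truth$hrc)), f_truth)
  out <- c(out, free_ensemble = f_pdb, free_truth = f_truth)

  cx <- sy$complex %||% list()
  ref <- generate_reference_complex(seqA, seqB, synthetic_interface(),
                                    chain_idp = cfg$chains$idp,
                                    chain_partner = cfg$chains$partner,
                                    seed = cfg$seed)
  r_pdb <- file.path(out_dir, "reference_complex.pdb")
  write_pdb_ensemble(ref, r_pdb)
  out <- c(out, reference = r_pdb)

  states <- cx$states %||% list(
    list(name = "F", fraction = 0.4, d_mean = 40, d_sd = 2, q_mean = 0, q_sd = 0),
    list(name = "E", fraction = 0.2, d_mean = 26, d_sd = 1.5, q_mean = 0, q_sd = 0),
    list(name = "B", fraction = 0.4, d_mean = 19, d_sd = 0.5, q_mean = 0.85,
         q_sd = 0.05)
  )
  mix <- tryCatch(
    state_mixture(vapply(states, `[[`, "", "name"),
                  vapply(states, `[[`, 0, "fraction"),
                  vapply(states, `[[`, 0, "d_mean"),
                  vapply(states, `[[`, 0, "d_sd"),
                  vapply(states, `[[`, 0, "q_mean"),
                  vapply(states, `[[`, 0, "q_sd")),
    error = function(e) config_error(conditionMessage(e)))
  .log(cfg, "info", "generating complex ensemble (", cx$n_frames %||% 400L,
       " frames)")
  gc_ <- generate_complex_ensemble(ref, mix, n_frames = cx$n_frames %||% 400L,
                                   seed = cfg$seed + 1L,
                                   chain_idp = cfg$chains$idp,
                                   chain_partner = cfg$chains$partner)
  c_pdb <- file.path(out_dir, "complex_ensemble.pdb")
  write_pdb_ensemble(gc_$ensemble, c_pdb)
  c_truth <- file.path(out_dir, "complex_truth.csv")
  write_csv_fixed(gc_$truth, c_truth)
  out <- c(out, complex_ensemble = c_pdb, complex_truth = c_truth)
  invisible(out)
}

#' Contact-map outputs of a config
#'
#' Intra-chain side-chain contact map and HRC count distribution of the
#' free ensemble; when a second free ensemble is given (e.g. the
#' unphosphorylated variant), also the contact-probability difference map.
#'
#' @param config an [read_run_config()] result (or path).
#' @param out_dir output directory.
#' @param ensemble,ensemble2 paths to multi-model PDB files; default to
#'   `config$inputs$free_ensemble` (and `$free_ensemble2`).
#' @return named character vector of written files, invisibly.
#' @export
pipeline_contacts <- function(config, out_dir,
                              ensemble = NULL, ensemble2 = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path1 <- ensemble %||% cfg$inputs$free_ensemble
  if (is.null(path1)) config_error("no free ensemble input configured")
  if (!file.exists(path1)) config_error("input file does not exist: ", path1)
  e1 <- read_pdb_ensemble(path1)
  if (!is.null(cfg$inputs$free_weights)) {
    e1 <- set_weights(e1, read_weights(cfg$inputs$free_weights, n_frames(e1)))
  }
  sel <- atom_selection(atoms = "side-chain-heavy")
  m1 <- contact_probability(e1, sel, sel, d_c = cfg$contact_cutoff)
  out <- c(contact_map = write_contact_map(m1, file.path(out_dir, "contact_map.csv")))
  dist <- hrc_count_distribution(e1, cfg$hrc_spec)
  out <- c(out, hrc_distribution = write_csv_fixed(
    dist, file.path(out_dir, "hrc_count_distribution.csv")))
  path2 <- ensemble2 %||% cfg$inputs$free_ensemble2
  if (!is.null(path2)) {
    if (!file.exists(path2)) config_error("input file does not exist: ", path2)
    e2 <- read_pdb_ensemble(path2)
    m2 <- contact_probability(e2, sel, sel, d_c = cfg$contact_cutoff)
    dm <- delta_contact(m1, m2)
    out <- c(out, delta_contact = write_contact_map(
      dm, file.path(out_dir, "delta_contact.csv")))
  }
  invisible(out)
}

#' Full ensemble-to-landscape analysis of a config
#'
#' Writes the helicity profile (with expanding-window uncertainties), and
#' -- when a complex ensemble plus reference are available -- the binding CV
#' table, the free-energy landscape (long-format CSV + JSON axis sidecar),
#' the basin table, per-state native/non-native contact maps, the HRC
#' probability projection, and a provenance-stamped summary.  Without
#' complex inputs the binding outputs are skipped with a logged notice.
#'
#' @param config an [read_run_config()] result (or path).
#' @param out_dir output directory.
#' @param free,complex,reference optional path overrides for the inputs.
#' @return named character vector of written files, invisibly.
#' @export
pipeline_analyze <- function(config, out_dir, free = NULL,
                             complex = NULL, reference = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  summary_lines <- c(
    "# idpfel analysis summary",
    paste0("# package version: ",
           as.character(utils::packageVersion("idpfel"))),
    paste0("# seed: ", cfg$seed),
    paste0("# temperature_K: ", cfg$temperature),
    paste0("# contact_cutoff_A: ", cfg$contact_cutoff),
    paste0("# hrc_residues: ", paste(cfg$hrc_spec$residues, collapse = " ")),
    paste0("# hrc_threshold: ", cfg$hrc_spec$threshold))

  free_path <- free %||% cfg$inputs$free_ensemble
  if (!is.null(free_path)) {
    if (!file.exists(free_path)) config_error("input file does not exist: ", free_path)
    .log(cfg, "info", "free-ensemble analysis: ", free_path)
    e <- read_pdb_ensemble(free_path)
    if (!is.null(cfg$inputs$free_weights)) {
      e <- set_weights(e, read_weights(cfg$inputs$free_weights, n_frames(e)))
    }
    prof <- expanding_window_error(e, chain = cfg$chains$idp)
    out <- c(out, helicity = write_csv_fixed(
      as.data.frame(prof), file.path(out_dir, "helicity.csv")))
    p_hrc <- hrc_probability(e, cfg$hrc_spec)
    summary_lines <- c(summary_lines, "",
                       paste0("free_frames: ", n_frames(e)),
                       paste0("hrc_probability: ", fmt_num(p_hrc)))
    for (rg in names(cfg$regions)) {
      summary_lines <- c(summary_lines, paste0(
        "helicity_", rg, ": ",
        fmt_num(region_helicity(prof, unlist(cfg$regions[[rg]])))))
    }
  }

  cplx_path <- complex %||% cfg$inputs$complex_ensemble
  ref_path <- reference %||% cfg$inputs$reference
  if (is.null(cplx_path) || is.null(ref_path)) {
    .log(cfg, "info",
         "no complex ensemble + reference configured; binding outputs skipped")
  } else {
    for (p in c(cplx_path, ref_path)) {
      if (!file.exists(p)) config_error("input file does not exist: ", p)
    }
    .log(cfg, "info", "binding analysis: ", cplx_path, " vs ", ref_path)
    ec <- read_pdb_ensemble(cplx_path)
    if (!is.null(cfg$inputs$complex_weights)) {
      ec <- set_weights(ec, read_weights(cfg$inputs$complex_weights, n_frames(ec)))
    }
    ref <- read_pdb_structure(ref_path)
    ncs <- native_contacts_from_reference(ref, cfg$chains$idp,
                                          cfg$chains$partner,
                                          d_c = cfg$contact_cutoff)
    cv <- cv_table(ec, ncs)
    out <- c(out, cv_table = write_csv_fixed(cv, file.path(out_dir, "cv_table.csv")))
    ax <- .fel_axes_from_config(cfg)
    fel <- weighted_fel(cv, ax$axis1, ax$axis2, temperature = cfg$temperature)
    grid <- expand.grid(cv1 = .axis_centers(fel$axis1),
                        cv2 = .axis_centers(fel$axis2))
    grid$free_energy <- as.vector(fel$f)
    names(grid)[1:2] <- c(fel$axis1$name, fel$axis2$name)
    grid$free_energy[!is.finite(grid$free_energy)] <- NA_real_
    out <- c(out, fel = write_csv_fixed(grid, file.path(out_dir, "fel.csv")))
    jsonlite::write_json(list(axis1 = fel$axis1[c("name", "min", "max", "width")],
                              axis2 = fel$axis2[c("name", "min", "max", "width")],
                              temperature_K = fel$temperature,
                              energy_cap = ax$energy_cap,
                              merge_barrier = ax$merge_barrier),
                         file.path(out_dir, "fel_axes.json"),
                         auto_unbox = TRUE, digits = NA)
    out <- c(out, fel_axes = file.path(out_dir, "fel_axes.json"))
    basins <- find_basins(fel, energy_cap = ax$energy_cap,
                          merge_barrier = ax$merge_barrier)
    out <- c(out, basins = write_csv_fixed(
      basins$minima, file.path(out_dir, "basins.csv")))
    labels <- suppressWarnings(assign_states(cv, basins))

    # HRC indicator projection on the landscape
    hrc_ind <- vapply(seq_len(n_frames(ec)), function(i) {
      is_hrc(get_frame(ec, i), cfg$hrc_spec)
    }, logical(1L))
    proj <- project_indicator(cv, hrc_ind, fel, energy_cap = ax$energy_cap)
    pg <- grid[, 1:2]
    pg$hrc_probability <- as.vector(proj)
    out <- c(out, hrc_projection = write_csv_fixed(
      pg, file.path(out_dir, "hrc_projection.csv")))

    summary_lines <- c(summary_lines, "",
                       paste0("complex_frames: ", n_frames(ec)),
                       paste0("native_contacts: ", nrow(ncs)),
                       paste0("n_basins: ", nrow(basins$minima)),
                       paste0("unassigned_frames: ", sum(is.na(labels))))
    for (b in basins$minima$label) {
      in_b <- !is.na(labels) & labels == b
      maps <- state_contact_map(ec, labels, b, ncs)
      nat_path <- file.path(out_dir, sprintf("state%02d_native_map.csv", b))
      non_path <- file.path(out_dir, sprintf("state%02d_nonnative_map.csv", b))
      write_contact_map(maps$native, nat_path)
      write_contact_map(maps$nonnative, non_path)
      out <- c(out, stats::setNames(c(nat_path, non_path),
                                    paste0(c("native_map_", "nonnative_map_"), b)))
      summary_lines <- c(summary_lines, paste0(
        "state_", b, ": n_frames=", sum(in_b),
        " mean_q=", fmt_num(stats::weighted.mean(cv$q[in_b], cv$weight[in_b])),
        " mean_d_com=", fmt_num(stats::weighted.mean(cv$d_com[in_b],
                                                     cv$weight[in_b])),
        " hrc_probability=", fmt_num(stats::weighted.mean(hrc_ind[in_b],
                                                          cv$weight[in_b]))))
    }
  }
  sum_path <- file.path(out_dir, "summary.txt")
  writeLines(summary_lines, sum_path)
  out <- c(out, summary = sum_path)
  invisible(out)
}

#' Run a pipeline command
#'
#' Thin dispatcher used by the command-line entry point: `"synth"`,
#' `"contacts"`, `"analyze"`, or `"all"` (synth, then contacts and analyze
#' wired to the synthetic outputs).
#'
#' @param command one of `synth`, `contacts`, `analyze`, `all`.
#' @param config path to a YAML config (or a config list).
#' @param out_dir output directory.
#' @return named character vector of written files, invisibly.
#' @export
pipeline_run <- function(command = c("all", "synth", "contacts", "analyze"),
                         config, out_dir) {
  command <- match.arg(command)
  cfg <- if (is.character(config)) read_run_config(config) else config
  switch(command,
    synth = pipeline_synth(cfg, out_dir),
    contacts = pipeline_contacts(cfg, out_dir),
    analyze = pipeline_analyze(cfg, out_dir),
    all = {
      files <- pipeline_synth(cfg, out_dir)
      out2 <- pipeline_contacts(cfg, out_dir, ensemble = files[["free_ensemble"]])
      out3 <- pipeline_analyze(cfg, out_dir,
                               free = files[["free_ensemble"]],
                               complex = files[["complex_ensemble"]],
                               reference = files[["reference"]])
      invisible(c(files, out2, out3))
    }
  )
}
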