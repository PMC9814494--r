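# Multi-model PDB ensemble I/O, weights and side tables.

write_toy_pdb <- function(path, models) {
  lines <- character(0)
  for (k in seq_along(models)) {
    lines <- c(lines, sprintf("MODEL     %4d", k))
    m <- models[[k]]
    for (i in seq_len(nrow(m))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, paste0(" ", m$elety[i]), m$resid[i], m$chain[i], m$resno[i],
        m$x[i], m$y[i], m$z[i], m$elesy[i]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
}

toy_model <- function(shift = 0) {
  data.frame(elety = c("N", "CA", "C", "N", "CA", "C", "N", "CA", "C"),
             resid = rep(c("ALA", "GLY", "SER"), each = 3L),
             chain = "A", resno = rep(1:3, each = 3L),
             x = seq(0, 8) * 1.3 + shift, y = rep(0.5, 9), z = rep(c(0, 1, 2), 3),
             elesy = rep(c("N", "C", "C"), 3L), stringsAsFactors = FALSE)
}

test_that("a two-model file round-trips with identical topology", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f, list(toy_model(0), toy_model(0.25)))
  e <- read_pdb_ensemble(f)
  expect_s3_class(e, "idp_ensemble")
  expect_equal(n_frames(e), 2L)
  expect_equal(n_atoms(e), 9L)
  expect_equal(e$atoms$elety, toy_model()$elety)
  expect_equal(e$atoms$resno, toy_model()$resno)
  expect_equal(frame_coords(e, 2L)[, 1L], toy_model(0.25)$x, tolerance = 1e-8)
  # a file without MODEL records is a one-frame ensemble
  f1 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(grep("^(MODEL|ENDMDL)", readLines(f), invert = TRUE, value = TRUE)[1:9], f1)
  expect_equal(n_frames(read_pdb_ensemble(f1)), 1L)
})

test_that("topology mismatches and bad coordinates are reported precisely", {
  f <- withr::local_tempfile(fileext = ".pdb")
  m2 <- toy_model()[-5L, ]  # model 2 lacks one atom
  write_toy_pdb(f, list(toy_model(), m2))
  expect_error(read_pdb_ensemble(f), "topology mismatch.*model 2")

  m3 <- toy_model(); m3$elety[2L] <- "CB"
  write_toy_pdb(f, list(toy_model(), m3))
  expect_error(read_pdb_ensemble(f), "topology mismatch.*atom 2")

  lines <- readLines({write_toy_pdb(f, list(toy_model())); f})
  substr(lines[3L], 31, 38) <- "  xx.yyy"
  writeLines(lines, f)
  expect_error(read_pdb_ensemble(f), "line 3")
})

test_that("write/read round-trip reproduces coordinates to format precision", {
  set.seed(7)
  g <- generate_free_ensemble(c(ALA = "ALA", LEU = "LEU", SER = "SER",
                                GLY = "GLY", VAL = "VAL"),
                              rep(0, 5L), n_frames = 100L, seed = 11)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(g$ensemble, f)
  e2 <- read_pdb_ensemble(f)
  expect_equal(n_frames(e2), 100L)
  expect_equal(e2$atoms$elety, g$ensemble$atoms$elety)
  expect_lt(max(abs(e2$xyz - g$ensemble$xyz)), 5.1e-4)
  # single frame writes MODEL 1 / ENDMDL / END
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(get_frame(g$ensemble, 1L), f1)
  lines <- readLines(f1)
  expect_match(lines[1L], "^MODEL")
  expect_true(any(grepl("^ENDMDL", lines)))
  expect_match(lines[length(lines)], "^END")
})

test_that("ensembles with zero frames or bad weights are rejected", {
  s <- build_conformer(c("ALA", "GLY"), c(FALSE, FALSE), seed = 1)
  expect_error(idp_ensemble(s$atoms, matrix(numeric(0), 0L, 3L * 6L)),
               "at least one frame")
  expect_error(idp_ensemble(s$atoms, list(s$xyz), weights = -1), ">= 0")
  expect_error(idp_ensemble(s$atoms, list(s$xyz), weights = 0), "positive sum")
})

test_that("weight tables are validated and never normalised at read time", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# frame weight", "1 1", "2 2", "3 3"), f)
  expect_equal(read_weights(f, 3L), c(1, 2, 3))
  writeLines(c("1,0.5", "2,0.5"), f)  # comma-separated works too
  expect_equal(read_weights(f, 2L), c(0.5, 0.5))
  writeLines(c("1 1", "2 -0.1", "3 1"), f)
  expect_error(read_weights(f, 3L), "negative weight")
  writeLines(c("1 0", "2 0"), f)
  expect_error(read_weights(f, 2L), "zero")
  writeLines(c("1 1", "3 1"), f)
  expect_error(read_weights(f, 3L), "missing")
})

test_that("selections are deterministic, class-correct and frame-invariant", {
  s <- build_conformer(c("GLY", "LEU", "SEP", "ALA"), rep(FALSE, 4L), seed = 3)
  # glycine has no side-chain heavy atoms
  expect_length(select_atoms(s, atom_selection(residues = 1L,
                                               atoms = "side-chain-heavy"),
                             warn_empty = FALSE), 0L)
  expect_warning(select_atoms(s, atom_selection(residues = 1L,
                                                atoms = "side-chain-heavy")),
                 "no atoms")
  # leucine side-chain heavy atoms are exactly CB, CG, CD1, CD2
  idx <- select_atoms(s, atom_selection(residues = 2L, atoms = "side-chain-heavy"))
  expect_setequal(s$atoms$elety[idx], c("CB", "CG", "CD1", "CD2"))
  expect_setequal(residue_heavy_atoms("LEU", "sidechain"),
                  c("CB", "CG", "CD1", "CD2"))
  # phosphoserine phosphate atoms count as side chain
  idx <- select_atoms(s, atom_selection(residues = 3L, atoms = "side-chain-heavy"))
  expect_true(all(c("P", "O1P", "O2P", "O3P") %in% s$atoms$elety[idx]))
  # alpha-carbon: one per residue
  expect_length(select_atoms(s, "alpha-carbon"), 4L)
  # hydrogens are excluded by element, whatever the name
  a <- s$atoms[1:2, ]; a$elety <- c("HX1", "CQ"); a$elesy <- c("H", "C")
  a$resno <- c(5L, 5L); a$resid <- "ALA"
  s2 <- idp_structure(rbind(s$atoms, a), rbind(s$xyz, matrix(99, 2L, 3L)))
  idx <- select_atoms(s2, atom_selection(residues = 5L, atoms = "all-heavy"))
  expect_equal(s2$atoms$elety[idx], "CQ")
  # same index set on every frame of an ensemble
  g <- generate_free_ensemble(c(A = "ALA", B = "LEU", C = "SER", D = "VAL"),
                              rep(0, 4L), n_frames = 4L, seed = 5)
  sel <- atom_selection(atoms = "side-chain-heavy")
  idx_e <- select_atoms(g$ensemble, sel)
  for (i in 1:4) {
    expect_identical(select_atoms(get_frame(g$ensemble, i), sel), idx_e)
  }
})

test_that("cluster and shift tables parse and validate", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# id F O", "1 0.0 2.5", "2, 3.1, 4.0"), f)
  ct <- read_cluster_table(f, temperature = 310)
  expect_s3_class(ct, "cluster_table")
  expect_equal(attr(ct, "temperature"), 310)
  expect_equal(ct$f_alpha, c(0, 3.1))
  writeLines(c("1 0 1", "1 2 3"), f)
  expect_error(read_cluster_table(f), "duplicate")
  writeLines(c("120 CA 58.3", "121 CA 57.1", "120 HA 4.2"), f)
  st <- read_shift_table(f)
  expect_equal(nrow(st), 3L)
  writeLines(c("120 CA 58.3", "120 CA 57.1"), f)
  expect_error(read_shift_table(f), "duplicate")
})
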