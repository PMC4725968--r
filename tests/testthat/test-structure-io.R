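test_that("PDB write/read round-trips coordinates at format precision", {
  h <- make_helix(20)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(h, f)
  h2 <- read_pdb(f)
  expect_equal(nrow(h2$atom), nrow(h$atom))
  expect_lt(max(abs(as.matrix(h$atom[, c("x", "y", "z")]) -
                      as.matrix(h2$atom[, c("x", "y", "z")]))), 1e-3)
  expect_equal(nrow(h2$helix), 1)
  # second round trip is exact (coordinates already quantized)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(h2, f2)
  h3 <- read_pdb(f2)
  expect_equal(as.matrix(h3$atom[, c("x", "y", "z")]),
               as.matrix(h2$atom[, c("x", "y", "z")]))
})

test_that("multi-MODEL files round-trip as ensembles", {
  e <- make_ensemble(make_helix(8), 3, 0.2, seed = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(e, f)
  e2 <- read_pdb(f)
  expect_equal(n_models(e2), 3)
  for (k in 1:3)
    expect_lt(max(abs(model_xyz(e, k) - model_xyz(e2, k))), 1e-3)
})

test_that("bad PDB input is rejected with line diagnostics", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(read_pdb(f), "empty")
  writeLines(c("ATOM      1  N   ALA A   1     bad coords here              N"),
             f)
  expect_error(read_pdb(f), "line 1")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40 10.00           N",
    "ATOM      2  N  BALA A   1       1.000   0.000   0.000  0.60 10.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.400   0.000  1.00 10.00           C",
    "END"), f)
  s <- read_pdb(f)
  expect_equal(sum(s$atom$elety == "N"), 1)
  expect_equal(s$atom$x[s$atom$elety == "N"], 1.0)
})

test_that("REMARK 350 transforms build the biological assembly on request", {
  h <- make_helix(6)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(h, f)
  rem <- c(
    "REMARK 350 BIOMOLECULE: 1",
    "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A",
    "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000",
    "REMARK 350   BIOMT1   2 -1.000000  0.000000  0.000000       20.00000",
    "REMARK 350   BIOMT2   2  0.000000 -1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   2  0.000000  0.000000  1.000000        0.00000")
  writeLines(c(rem, readLines(f)), f)
  s <- read_pdb(f, biounit = TRUE)
  expect_equal(length(chain_ids(s)), 2)
})

test_that("select_assembly restricts chains and validates ids", {
  d <- make_toy_dimer(8)
  m <- select_assembly(d, "A")
  expect_equal(chain_ids(m), "A")
  both <- select_assembly(d, c("A", "B"))
  expect_equal(both$atom, d$atom)
  expect_error(select_assembly(d, "Z"), "available")
})

test_that("secondary structure: heuristic, record precedence, extended chain", {
  h <- make_helix(20)
  h$helix <- NULL
  h <- assign_secondary_structure(h)
  expect_true(all(h$sse$sse == "H"))
  expect_equal(nrow(h$elements), 1)

  # records win over dihedrals
  h2 <- make_helix(20)
  h2$helix <- data.frame(chain = "A", start = 3, end = 10)
  h2$sheet <- data.frame(chain = "A", start = 12, end = 15)
  h2 <- assign_secondary_structure(h2)
  expect_true(all(h2$sse$sse[3:10] == "H"))
  expect_true(all(h2$sse$sse[12:15] == "E"))

  # fully extended chain is never helix
  g <- rignet:::helix_geometry
  N <- list(c(0, 0, 0)); CA <- list(c(1.458, 0, 0))
  C <- list(CA[[1]] + 1.525 * c(cos(pi * 69 / 180), sin(pi * 69 / 180), 0))
  for (i in 2:8) {
    N[[i]] <- rignet:::place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]], g$b_c_n,
                                  g$a_ca_c_n, 180)
    CA[[i]] <- rignet:::place_atom(CA[[i - 1]], C[[i - 1]], N[[i]], g$b_n_ca,
                                   g$a_c_n_ca, 180)
    C[[i]] <- rignet:::place_atom(C[[i - 1]], N[[i]], CA[[i]], g$b_ca_c,
                                  g$a_n_ca_c, 180)
  }
  rows <- lapply(1:8, function(i) rbind(
    atom_row("N", "N", "GLY", "A", i, N[[i]][1], N[[i]][2], N[[i]][3]),
    atom_row("CA", "C", "GLY", "A", i, CA[[i]][1], CA[[i]][2], CA[[i]][3]),
    atom_row("C", "C", "GLY", "A", i, C[[i]][1], C[[i]][2], C[[i]][3])))
  ext <- do.call(mini_structure, rows)
  ext <- assign_secondary_structure(ext)
  expect_true(all(ext$sse$sse %in% c("E", "C")))
})

test_that("secondary structure assignment is rigid-motion invariant", {
  h <- make_helix(15)
  h$helix <- NULL
  a <- assign_secondary_structure(h)$sse$sse
  b <- assign_secondary_structure(transform_structure(h))$sse$sse
  expect_identical(a, b)
})

test_that("relative B-factors are per-chain z-scores", {
  s <- make_helix(5)
  s$atom <- s$atom[s$atom$elety == "CA", ][1:3, ]
  s$atom$b <- c(10, 20, 30)
  z <- relative_bfactors(s, "all")
  expect_equal(z$z, c(-1.224745, 0, 1.224745), tolerance = 1e-6)

  expect_error({
    s2 <- s; s2$atom$b <- 15
    relative_bfactors(s2, "all")
  }, "identical")

  # appending a duplicate chain leaves per-chain z-scores unchanged
  dup <- s
  b_atoms <- s$atom; b_atoms$chain <- "B"
  dup$atom <- rbind(s$atom, b_atoms)
  zz <- relative_bfactors(dup, "all")
  expect_equal(zz$z[zz$chain == "A"], z$z)
  expect_equal(zz$z[zz$chain == "B"], z$z)
})
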