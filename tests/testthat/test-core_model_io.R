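# Domain types, file I/O, ensemble bookkeeping.

test_that("molecule construction enforces its invariants", {
  atoms <- atom_table(c("N", "H", "C"))
  expect_s3_class(molecule(atoms, rbind(c(1L, 2L), c(1L, 3L))), "molecule")
  # donor-H must be a hydrogen bonded to N/O/S
  atoms_bad <- atom_table(c("C", "H", "C"), is_hb_donor_h = c(FALSE, TRUE, FALSE))
  expect_error(molecule(atoms_bad, rbind(c(2L, 3L))), "N/O/S")
  expect_error(molecule(atoms, rbind(c(1L, 9L))), "out of range")
  expect_error(
    molecule(atoms, rbind(c(1L, 2L)), proton_groups = list(g = c(1L))),
    "non-hydrogen")
  # conformer/library consistency
  expect_error(conformer(matrix(c(0, 0, NA), 1), "x"), "non-finite")
  expect_error(
    conformer_library(molecule(atoms, rbind(c(1L, 2L))),
                      list(conformer(matrix(0, 2, 3)))),
    "2 atoms")
})

test_that("structure formats round-trip coordinates", {
  spec <- generator_spec(n_conformers = 3, noise_sigma_xyz = 0.2, seed = 2)
  mol <- build_model_protac(spec)
  lib <- generate_ensemble(mol, spec)$library
  for (fmt in c("pdb", "sdf", "xyz")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_conformer_library(lib, path, fmt)
    back <- suppressWarnings(read_conformer_library(path, fmt))
    expect_equal(n_conformers(back), 3)
    expect_equal(n_atoms(back$molecule), n_atoms(mol))
    tol <- if (fmt == "pdb") 1e-3 else 1e-4
    for (k in 1:3) {
      expect_lt(max(abs(coords_of(back, k) - coords_of(lib, k))), tol + 1e-9)
    }
    expect_identical(back$molecule$atoms$element, mol$atoms$element)
  }
  # SDF carries partial charges through the data field
  path <- withr::local_tempfile(fileext = ".sdf")
  write_conformer_library(lib, path, "sdf")
  back <- read_conformer_library(path, "sdf")
  expect_equal(back$molecule$atoms$charge, mol$atoms$charge, tolerance = 1e-8)
})

test_that("multi-model PDB reading preserves counts and flags bad models", {
  lines <- character(0)
  for (m in 1:3) {
    natom <- if (m == 2) 9 else 10   # model 2 drops an atom
    lines <- c(lines, sprintf("MODEL     %4d", m),
      sprintf("HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
              1:natom, paste0("C", 1:natom), (1:natom) * 1.0, m * 1.0, 0),
      "ENDMDL")
  }
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), bad)
  expect_error(suppressWarnings(read_conformer_library(bad, "pdb")),
               "model 2")
  # consistent 3 x 10 file reads as 3 conformers of 10 atoms
  lines <- character(0)
  for (m in 1:3) {
    lines <- c(lines, sprintf("MODEL     %4d", m),
      sprintf("HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
              1:10, paste0("C", 1:10), (1:10) * 1.0, m * 1.0, 0),
      "ENDMDL")
  }
  good <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), good)
  lib <- suppressWarnings(read_conformer_library(good, "pdb"))
  expect_equal(n_conformers(lib), 3)
  expect_equal(n_atoms(lib$molecule), 10)
})

test_that("deduplication matches a brute-force greedy oracle", {
  # identical conformers collapse; distant ones survive
  a <- matrix(rnorm(30), 10, 3)
  lib2 <- make_library(list(a, a))
  expect_equal(n_conformers(deduplicate_conformers(lib2, 3)), 1)
  b <- a + 10  # translation only: RMSD 0 after superposition
  expect_equal(n_conformers(deduplicate_conformers(make_library(list(a, b)), 3)), 1)

  # random 20-conformer library vs an oracle built from bio3d RMSDs
  set.seed(31)
  confs <- lapply(1:20, function(i) matrix(rnorm(30, sd = 2), 10, 3))
  lib <- make_library(confs)
  cutoff <- 3
  oracle_rmsd <- function(x, y) {
    fx <- suppressWarnings(
      bio3d::fit.xyz(as.vector(t(x)), matrix(as.vector(t(y)), 1)))
    sqrt(mean(rowSums((matrix(fx, ncol = 3, byrow = TRUE) - x)^2)))
  }
  kept <- integer(0)
  for (k in 1:20) {
    if (all(vapply(kept, function(j) oracle_rmsd(confs[[j]], confs[[k]]),
                   numeric(1)) > cutoff)) {
      kept <- c(kept, k)
    }
  }
  dd <- deduplicate_conformers(lib, cutoff, heavy_only = FALSE)
  expect_identical(attr(dd, "kept"), kept)
  # idempotence
  dd2 <- deduplicate_conformers(dd, cutoff, heavy_only = FALSE)
  expect_equal(n_conformers(dd2), n_conformers(dd))
})

test_that("search completeness follows the closed form and its limits", {
  expect_equal(search_completeness(1, 1), 1.0)
  expect_equal(search_completeness(2, 1), 0.5)
  expect_equal(search_completeness(1000, 5000), 0.99328, tolerance = 1e-5)
  expect_error(search_completeness(0, 10), ">= 1")
  # monotone in M, decreasing in N, limit 1
  m <- search_completeness(50, c(10, 100, 1000, 1e6))
  expect_true(all(diff(m) > 0))
  expect_true(search_completeness(10, 100) > search_completeness(100, 100))
  expect_equal(search_completeness(5, 1e5), 1.0)
})

test_that("weighted mean matches hand sums and rejects bad weights", {
  expect_equal(weighted_mean(c(200, 300), c(0.5, 0.5)), 250)
  expect_equal(weighted_mean(7.3, 0.2), 7.3)
  expect_equal(weighted_mean(c(1, 2, 3), c(0.2, 0.3, 0.5)), 2.3)
  expect_error(weighted_mean(c(1, 2), c(0, 0)), "zero")
  expect_error(weighted_mean(c(1, 2), c(1, -1)), "non-negative")
})
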