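# A small hand-written PDB text fixture: one ALA (with hydrogens and an
# altloc'd CB), one LEU, a water and a heme-like hetero atom.
pdb_fixture_lines <- function(with_hydrogens = TRUE, shuffle = FALSE) {
  ala <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB AALA A   1       1.988  -0.773  -1.199  0.40  0.00           C",
    "ATOM      6  CB BALA A   1       1.970  -0.760  -1.210  0.60  0.00           C"
  )
  hyd <- c(
    "ATOM      7  H   ALA A   1      -0.500   0.800   0.000  1.00  0.00           H",
    "ATOM      8  HA  ALA A   1       1.800  -0.500   0.900  1.00  0.00           H"
  )
  leu <- c(
    "ATOM      9  N   LEU A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM     10  CA  LEU A   2       4.021   2.820   0.000  1.00  0.00           C",
    "ATOM     11  C   LEU A   2       5.530   2.625   0.000  1.00  0.00           C",
    "ATOM     12  O   LEU A   2       6.010   1.490   0.000  1.00  0.00           O",
    "ATOM     13  CB  LEU A   2       3.600   3.640   1.230  1.00  0.00           C",
    "ATOM     14  CG  LEU A   2       4.100   5.090   1.300  1.00  0.00           C",
    "ATOM     15  CD1 LEU A   2       3.600   5.800   2.560  1.00  0.00           C",
    "ATOM     16  CD2 LEU A   2       5.630   5.130   1.290  1.00  0.00           C"
  )
  het <- c(
    "HETATM   17 FE   HEM A 101       8.000   8.000   8.000  1.00  0.00          FE",
    "HETATM   18  O   HOH A 201       9.000   9.000   9.000  1.00  0.00           O"
  )
  if (shuffle) leu <- leu[c(3, 1, 6, 2, 8, 4, 5, 7)]
  body <- c(ala, if (with_hydrogens) hyd, leu, het)
  c(body, "END")
}

write_pdb_fixture <- function(..., file = tempfile(fileext = ".pdb")) {
  writeLines(pdb_fixture_lines(...), file)
  file
}

radius_table_fe <- function() {
  c(default_radius_table(), FE = 2.0)
}

test_that("read_pdb builds the sphere model: partition, hydrogens, waters, altloc", {
  mol <- read_pdb(write_pdb_fixture(), radius_table = radius_table_fe())
  expect_s3_class(mol, "tf_molecule")
  expect_named(mol$residues, c("A:1", "A:2"))

  ala <- mol$residues[["A:1"]]
  expect_equal(nrow(ala$main_chain), 4L)
  expect_equal(ala$side_chain$name, "CB")
  expect_false(ala$rotatable) # ALA: CB on the axis, rotation is identity
  # altloc resolved to the higher-occupancy B copy
  expect_equal(ala$side_chain$x, 1.970)

  leu <- mol$residues[["A:2"]]
  expect_setequal(leu$side_chain$name, c("CB", "CG", "CD1", "CD2"))
  expect_true(leu$rotatable)
  expect_equal(leu$axis$point_a, c(4.021, 2.820, 0))
  expect_equal(leu$axis$point_b, c(3.600, 3.640, 1.230))

  # water dropped, hetero iron kept as obstacle with its table radius
  expect_equal(mol$hetero$name, "FE")
  expect_equal(mol$hetero$radius, 2.0)
  no_het <- read_pdb(write_pdb_fixture(), radius_table = radius_table_fe(),
                     keep_hetero = FALSE)
  expect_equal(nrow(no_het$hetero), 0L)
})

test_that("hydrogens never change the parsed model", {
  tab <- radius_table_fe()
  with_h <- read_pdb(write_pdb_fixture(with_hydrogens = TRUE),
                     radius_table = tab)
  without_h <- read_pdb(write_pdb_fixture(with_hydrogens = FALSE),
                        radius_table = tab)
  expect_identical(with_h, without_h)
})

test_that("residue content is invariant under record order within a residue", {
  tab <- radius_table_fe()
  a <- read_pdb(write_pdb_fixture(), radius_table = tab)
  b <- read_pdb(write_pdb_fixture(shuffle = TRUE), radius_table = tab)
  expect_identical(names(a$residues), names(b$residues))
  for (key in names(a$residues)) {
    ra <- a$residues[[key]]; rb <- b$residues[[key]]
    expect_identical(ra$rotatable, rb$rotatable)
    ord_a <- order(ra$side_chain$name); ord_b <- order(rb$side_chain$name)
    expect_identical(ra$side_chain[ord_a, ], rb$side_chain[ord_b, ],
                     ignore_attr = TRUE)
    expect_identical(ra$axis, rb$axis)
  }
})

test_that("read_pdb errors are informative", {
  bad <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), bad)
  expect_error(read_pdb(bad), "ATOM")
  expect_error(read_pdb(tempfile()), "cannot read")
  # iron present but no FE entry in the default table
  expect_error(read_pdb(write_pdb_fixture()), "FE")
  expect_error(read_pdb(write_pdb_fixture(), model = 2), "model")
})

test_that("radius assignment follows the active table", {
  expect_equal(default_radius_table()[["C"]], 1.70)
  expect_equal(default_radius_table()[["S"]], 1.80)
  bundled <- read_radius_table(
    system.file("extdata", "vdw_bondi.tsv", package = "tunnelflex")
  )
  expect_equal(unname(bundled["C"]), 1.70)

  mol <- read_pdb(write_pdb_fixture(), radius_table = radius_table_fe())
  carbons <- mol$residues[["A:2"]]$side_chain
  expect_true(all(carbons$radius == 1.70))
  custom <- c(C = 2.0, N = 2.0, O = 2.0, S = 2.0, FE = 2.0)
  mol2 <- assign_radii(mol, custom)
  expect_true(all(mol2$residues[["A:2"]]$side_chain$radius == 2.0))
  expect_error(assign_radii(mol, c(C = 1.7, N = 1.55, O = 1.52)), "S")
  expect_error(
    assign_radii(mol, c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)), "FE"
  )
})

test_that("partition_residue classifies atoms and flags rotatability", {
  gly <- data.frame(
    serial = 1:4, name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
    x = c(0, 1.4, 2, 1.2), y = c(0, 0, 1.4, 2.4), z = 0, radius = 1.6,
    stringsAsFactors = FALSE
  )
  r <- partition_residue(gly, "GLY")
  expect_equal(nrow(r$side_chain), 0L)
  expect_false(r$rotatable)
  expect_null(r$axis)

  dup <- rbind(gly, gly[2L, ])
  expect_error(partition_residue(dup, "GLY"), "duplicate")
})

test_that("tunnel dialect round-trips bit-exactly in TSV and JSON", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("t\tx\ty\tz\tr",
               "0\t0\t0\t0\t1.5",
               "0.5\t1\t0.25\t-0.125\t1.1",
               "1\t2\t0.5\t0.3333333333333333\t2.25"), f)
  tun <- read_tunnel(f)
  expect_equal(nrow(tun$samples), 3L)
  expect_equal(tun$samples$r, c(1.5, 1.1, 2.25))

  out_tsv <- tempfile(fileext = ".tsv")
  write_tunnel(tun, out_tsv)
  expect_identical(read_tunnel(out_tsv)$samples, tun$samples)
  out_json <- tempfile(fileext = ".json")
  write_tunnel(tun, out_json, format = "json")
  expect_equal(read_tunnel(out_json)$samples, tun$samples)
})

test_that("tunnel dialect contract violations are rejected", {
  write_lines_tmp <- function(lines) {
    f <- tempfile(fileext = ".tsv")
    writeLines(lines, f)
    f
  }
  expect_error(read_tunnel(write_lines_tmp(
    c("t\tx\ty\tz\tr", "0\t0\t0\t0\t1", "0\t1\t0\t0\t1")
  )), "increasing")
  expect_error(read_tunnel(write_lines_tmp(
    c("t\tx\ty\tz\tr", "0\t0\t0\t0\t1", "0.5\t1\t0\t0\t0")
  )), "positive")
  expect_error(read_tunnel(write_lines_tmp(
    c("t\tx\ty\tz\tr", "0\t0\t0\t0\t1")
  )), "2 samples")
  expect_error(read_tunnel(write_lines_tmp(
    c("t\tx\ty\tr", "0\t0\t0\t1", "1\t1\t0\t1")
  )), "columns")
})
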