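test_that("XYZ round-trip is lossless at the stated precision", {
  w <- makeWater()
  path <- withr::local_tempfile(fileext = ".xyz")
  writeXYZ(w, path)
  back <- readXYZ(path)
  expect_equal(atoms(back)$label, atoms(w)$label)
  expect_equal(atoms(back)$element, atoms(w)$element)
  expect_equal(as.matrix(atoms(back)[, c("x", "y", "z")]),
               as.matrix(atoms(w)[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("XYZ reader handles single atoms, labels, energies and errors", {
  path <- withr::local_tempfile(fileext = ".xyz")
  # bare element symbols: labels auto-generated, masses from the table
  writeLines(c("2", "comment E_rel=0.500", "H 0 0 0", "C 1.1 0 0"), path)
  conf <- readXYZ(path)
  expect_equal(atoms(conf)$label, c("H1", "C2"))
  expect_equal(atoms(conf)$mass[1], 1.008, tolerance = 0.01)
  expect_equal(atoms(conf)$mass[2], 12.011, tolerance = 0.01)
  expect_equal(relEnergy(conf), 0.5)

  # count mismatch names the problem
  writeLines(c("2", "c", "H 0 0 0", "H 1 0 0", "H 2 0 0"), path)
  expect_error(readXYZ(path), class = "rdcXYZCountError")
  # unknown element
  writeLines(c("1", "c", "Xx 0 0 0", ""), path)
  expect_error(readXYZ(path), class = "rdcElementError")
  # coordinate parse failure
  writeLines(c("1", "c", "H 0 zero 0"), path)
  expect_error(readXYZ(path), class = "rdcXYZCoordError")
})

test_that("standard atomic weights match reference values", {
  expect_equal(atomicMass(c("C", "H", "N", "O")),
               c(12.011, 1.008, 14.007, 15.999), tolerance = 0.01)
})

test_that("RDC table round-trips, including the NA sentinel", {
  ds <- rdcDataset(atom1 = c("C7", "C8", "C9"),
                   atom2 = c("H7", "H8", "H9"),
                   type = c("CH", "CH", "CH3-methyl"),
                   J = c(125, NA, 128.5), sigJ = c(0.2, NA, 0.25),
                   T = c(145, NA, 120.12), sigT = c(0.3, NA, 0.4),
                   D = c(10, -4.25, NA), sigD = c(0.18, 0.3, NA),
                   include = c(TRUE, FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRDCTable(ds, path)
  back <- readRDCTable(path)
  expect_equal(records(back)$atom1, records(ds)$atom1)
  expect_equal(records(back)$D, records(ds)$D, tolerance = 0.005)
  expect_equal(records(back)$J, records(ds)$J, tolerance = 0.005)
  expect_identical(records(back)$include, records(ds)$include)
  expect_true(is.na(records(back)$J[2]) && is.na(records(back)$D[3]))
})

test_that("RDC table parsing maps rows and flags malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "atom1 atom2 type J sigJ T sigT",
               "C7 H7 CH 125.0 0.2 145.0 0.3"), path)
  ds <- readRDCTable(path)
  r <- records(ds)
  expect_equal(r$J, 125.0)
  expect_equal(r$T, 145.0)
  expect_true(r$include)          # include defaults to TRUE
  expect_true(is.na(r$D))

  # row missing a trailing field is reported with its line number
  writeLines(c("atom1 atom2 D sigD", "C7 H7 10.0 0.2", "C8 8.0 0.2"), path)
  expect_error(readRDCTable(path), "line 3", class = "rdcTableError")
  # non-numeric coupling cell
  writeLines(c("atom1 atom2 D sigD", "C7 H7 ten 0.2"), path)
  expect_error(readRDCTable(path), class = "rdcTableError")
  # mandatory columns
  writeLines(c("atom1 D", "C7 10.0"), path)
  expect_error(readRDCTable(path), class = "rdcTableError")
})

test_that("empty dataset writes a header-only re-readable file", {
  ds <- new("RDCDataset",
            records = rdcDataset("a", "b", D = 1, sigD = 0.1)@records[0, ])
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRDCTable(ds, path)
  expect_length(readLines(path), 1)
  expect_equal(nrow(records(readRDCTable(path))), 0)
})

test_that("dataset invariants are enforced", {
  # record with no coupling value at all
  expect_error(rdcDataset("C1", "H1"), "coupling value")
  # non-positive sigma
  expect_error(rdcDataset("C1", "H1", D = 5, sigD = -0.1), "positive")
  # a J-only record survives I/O but cannot be fitted
  ds <- rdcDataset(paste0("C", 1:5), paste0("H", 1:5),
                   J = c(NA, 140, 141, 142, 143),
                   T = c(150, 151, 152, 153, NA),
                   D = c(5, NA, NA, NA, NA))
  case <- makeRigidCase(n = 5, seed = 77)
  expect_error(fitSCST(case$conf, ds), class = "rdcFitError")
})

test_that("PDB subset reader uses first model, names and coordinates", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "HETATM", 1, " C1", "LIG", "A", 1, 0, 0, 0, 1, 0, "C"),
    sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "HETATM", 2, " H1", "LIG", "A", 1, 1.09, 0, 0, 1, 0, "H"),
    "ENDMDL",
    "MODEL        2",
    sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "HETATM", 3, " C1", "LIG", "A", 1, 9, 9, 9, 1, 0, "C"),
    "ENDMDL"), path)
  conf <- readPDB(path)
  expect_equal(nrow(atoms(conf)), 2)       # second MODEL ignored
  expect_equal(atoms(conf)$label, c("C1", "H1"))
  expect_equal(atoms(conf)$x, c(0, 1.09), tolerance = 1e-6)
})

test_that("population table round-trips through the delimited dialect", {
  tbl <- makeEnsembleTable()
  tbl <- assignGroups(tbl, list(A = c("01", "02"), B = c("03", "04")))
  path <- withr::local_tempfile(fileext = ".tsv")
  writePopulationTable(tbl, path)
  back <- readPopulationTable(path)
  expect_equal(conformerTable(back)$pRaw, conformerTable(tbl)$pRaw,
               tolerance = 1e-4)
  expect_equal(conformerTable(back)$group, conformerTable(tbl)$group)
})
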