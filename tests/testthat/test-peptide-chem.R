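test_that("notation parsing handles termini and round-trips exactly", {
  p <- parseAkhNotation("pELTFTSSWGa")
  expect_s4_class(p, "AkhPeptide")
  expect_identical(residues(p), c("E", "L", "T", "F", "T", "S", "S", "W", "G"))
  expect_identical(nTerm(p), "pyroglutamate")
  expect_identical(cTerm(p), "amide")

  v <- parseAkhNotation("pELTFTSSWGGK-OH")
  expect_identical(length(v), 11L)
  expect_identical(cTerm(v), "free_acid")

  for (nt in c(CONFIRMED_AKHS, VANCA))
    expect_identical(formatAkhNotation(parseAkhNotation(nt)), nt)
})

test_that("malformed notation raises distinct, named parse errors", {
  expect_error(parseAkhNotation("ELTFTSSWGa"), "missing 'pE' prefix")
  expect_error(parseAkhNotation("pELTFXSSWGa"), "unknown residue code 'X'")
  expect_error(parseAkhNotation("pELTFTSSWG"), "missing terminus marker")
  expect_error(parseAkhNotation(""), "empty")
})

test_that("residue masses match the published HRMS discrimination values", {
  expect_equal(round(residueMass("Q"), 4), 128.0586)
  expect_equal(round(residueMass("K"), 4), 128.0950)
  expect_equal(round(residueMass("Q") - residueMass("K"), 4), -0.0364)
  ## glycine from first principles: C2 H3 N O with standard atomic masses
  gly <- 2 * 12 + 3 * 1.0078250319 + 14.0030740052 + 15.9949146221
  expect_equal(residueMass("G"), gly, tolerance = 1e-9)
  expect_equal(round(residueMass("G"), 4), 57.0215)
  expect_error(residueMass("X"), "unknown residue")
})

test_that("residue composition masses agree with the mass table", {
  for (code in c(rownames(akhpep:::.RESIDUE_COMPOSITIONS), "pE"))
    expect_equal(compositionMass(residueComposition(code)),
                 residueMass(code), tolerance = 1e-6)
})

test_that("ionized compositions reproduce the printed elemental formulas", {
  expect_identical(
    hillFormula(peptideComposition(parseAkhNotation("pELTFSSGWGQa"), "H")),
    "C50H70N13O15")
  expect_identical(
    hillFormula(peptideComposition(parseAkhNotation("pELTFSSGWGKa"), "H")),
    "C51H74N13O14")
  expect_identical(
    hillFormula(peptideComposition(parseAkhNotation("pELTFSPGWGQa"), "H")),
    "C52H72N13O14")
})

test_that("protonated masses reproduce printed catalog values to 4 d.p.", {
  for (nm in names(CONFIRMED_AKHS)) {
    mz <- ionMz(parseAkhNotation(CONFIRMED_AKHS[[nm]]), "H")
    expect_lt(abs(mz - PRINTED_MH[[nm]]), 5e-4)
  }
  expect_equal(round(ionMz(parseAkhNotation(VANCA), "H"), 4), 1194.5790)
  ## ammonium adduct of Manse-AKH, seen at low resolution as 1025.4
  expect_equal(round(ionMz(parseAkhNotation("pELTFTSSWGa"), "NH4"), 1), 1025.5)
})

test_that("adduct shifts and composition/mass routes are mutually consistent", {
  for (nt in CONFIRMED_AKHS) {
    p <- parseAkhNotation(nt)
    ## NH4 vs H differ by neutral ammonia
    expect_equal(ionMz(p, "NH4") - ionMz(p, "H"), 17.026549, tolerance = 1e-5)
    ## two independent computations of the protonated mass
    expect_equal(compositionMass(peptideComposition(p, "H")) +
                   (1.007276 - 1.0078250319),  # proton vs H atom
                 ionMz(p, "H"), tolerance = 1e-5)
  }
  ## appending one Gly: Lacol - Manse and Triin - Peram-CAH-II
  gly <- residueMass("G")
  expect_equal(ionMz(parseAkhNotation("pELTFTSSWGGa")) -
                 ionMz(parseAkhNotation("pELTFTSSWGa")), gly,
               tolerance = 1e-9)
  expect_equal(ionMz(parseAkhNotation("pELTFTPNWGa")) -
                 ionMz(parseAkhNotation("pELTFTPNWa")), gly,
               tolerance = 1e-9)
})

test_that("ppm error is signed and guards its domain", {
  expect_equal(ppmError(1092.5109, 1092.5109), 0)
  expect_equal(round(ppmError(1092.5100, 1092.5109), 2), -0.82)
  expect_error(ppmError(100, 0), "positive")
})

test_that("FASTA export carries terminus tags and round-trips", {
  peps <- lapply(c(CONFIRMED_AKHS[1:3], VANCA), parseAkhNotation)
  path <- withr::local_tempfile(fileext = ".fasta")
  writeAkhFasta(peps, path)
  txt <- readLines(path)
  expect_true(any(grepl("nterm=pGlu cterm=amide", txt)))
  expect_true(any(grepl("nterm=pGlu cterm=free", txt)))
  back <- readAkhFasta(path)
  expect_identical(vapply(back, formatAkhNotation, character(1)),
                   vapply(peps, formatAkhNotation, character(1),
                          USE.NAMES = FALSE) |> setNames(names(back)))
})

test_that("peptide validity rules reject inconsistent objects", {
  expect_error(AkhPeptide("LTFT", nTerm = "pyroglutamate"),
               "residue 1 to be E")
  expect_error(AkhPeptide(character(0)), "at least one residue")
  expect_error(AkhPeptide("EXT"), "unknown residue")
})
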