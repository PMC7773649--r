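manse <- parseAkhNotation("pELTFTSSWGa")

test_that("fragment ladder has n-1 ions per series with correct anchors", {
  fl <- fragmentLadder(manse, series = c("b", "y"), losses = "none")
  expect_identical(nrow(fl), 16L)                     # 8 b + 8 y for n = 9
  expect_true(!is.unsorted(fl$mz))
  ## b2 = pGlu + Leu + proton; y1 = Gly + NH3 + proton (amide C-terminus)
  expect_equal(round(fl$mz[fl$label == "b2"], 4), 225.1234)
  expect_equal(round(fl$mz[fl$label == "y1"], 4), 75.0553)
  ## neutral losses shift by exactly the water/ammonia masses
  fl2 <- fragmentLadder(manse, losses = c("none", "H2O", "NH3"))
  b3 <- fl2$mz[fl2$label == "b3"]
  expect_equal(b3 - fl2$mz[fl2$label == "b3-H2O"], 18.010565, tolerance = 1e-9)
  expect_equal(b3 - fl2$mz[fl2$label == "b3-NH3"], 17.026549, tolerance = 1e-9)
  expect_error(fragmentLadder(AkhPeptide("G", nTerm = "free")), "length >= 2")
})

test_that("b/y pairs conserve the precursor mass across every cleavage", {
  for (nt in c(CONFIRMED_AKHS, VANCA)) {
    p <- parseAkhNotation(nt)
    fl <- fragmentLadder(p, losses = "none")
    n <- length(p)
    target <- ionMz(p, "H") + 1.007276
    for (i in seq_len(n - 1L)) {
      bi <- fl$mz[fl$series == "b" & fl$index == i]
      yni <- fl$mz[fl$series == "y" & fl$index == n - i]
      expect_equal(bi + yni, target, tolerance = 1e-5)
    }
  }
})

test_that("Leu/Ile variants are invisible to fragmentation", {
  a <- fragmentLadder(parseAkhNotation("pELTFTPNWa"))
  b <- fragmentLadder(parseAkhNotation("pEITFTPNWa"))
  expect_equal(a$mz, b$mz, tolerance = 1e-12)
})

test_that("self-annotation is complete and empty spectra degrade cleanly", {
  lacol <- parseAkhNotation("pELTFTSSWGGa")
  fl <- fragmentLadder(lacol, losses = c("none", "H2O", "NH3"))
  s <- CidSpectrum(ionMz(lacol), fl$mz, rep(100, nrow(fl)))
  a <- annotateSpectrum(s, lacol, tol = 0.3)
  expect_equal(a$coverage, 1.0)
  expect_identical(a$unmatchedPeaks, 0L)
  expect_identical(nrow(a$matches), nrow(fl))

  empty <- CidSpectrum(ionMz(lacol))
  expect_equal(annotateSpectrum(empty, lacol)$coverage, 0)
  expect_error(annotateSpectrum(s, lacol, tol = 0), "positive")
})

test_that("annotation coverage is monotone non-decreasing in tolerance", {
  set.seed(42)
  s <- simulateCid(manse, cidSimParams(jitterSd = 0.15), seed = 9)
  cov <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4),
                function(tol) annotateSpectrum(s, manse, tol)$coverage,
                numeric(1))
  expect_true(all(diff(cov) >= 0))
})

test_that("each peak is matched at most once, closest ion wins", {
  ## two theoretical ions but only one observed peak between them
  fl <- fragmentLadder(manse, losses = "none")
  s <- CidSpectrum(ionMz(manse), fl$mz[3] + 0.01, 100)
  a <- annotateSpectrum(s, manse, tol = 0.5)
  expect_identical(nrow(a$matches), 1L)
  expect_equal(a$matches$theoreticalMz, fl$mz[3], tolerance = 1e-9)
})

test_that("match score is deterministic and permutation-invariant", {
  s <- simulateCid(manse, seed = 5)
  sc1 <- matchScore(s, manse)
  perm <- sample(seq_along(s@mz))
  s2 <- CidSpectrum(precursorMz(s), s@mz[perm], s@intensity[perm])
  expect_identical(matchScore(s2, manse), sc1)

  ## the true peptide scores maximally against its own noiseless ladder
  fl <- fragmentLadder(manse, losses = c("none", "H2O", "NH3"))
  clean <- CidSpectrum(ionMz(manse), fl$mz, rep(1, nrow(fl)))
  scores <- vapply(CONFIRMED_AKHS, function(nt)
    matchScore(clean, parseAkhNotation(nt)), numeric(1))
  expect_identical(names(which.max(scores)), "Manse-AKH")

  ## simulated Helze-HrTH spectrum prefers Helze-HrTH over Manse-AKH
  helze <- parseAkhNotation("pELTFSSGWGNa")
  s7 <- simulateCid(helze, seed = 7)
  expect_gt(matchScore(s7, helze), matchScore(s7, manse))
})

test_that("isobaric ambiguity reporting follows the tolerance arithmetic", {
  makh2 <- parseAkhNotation("pELTFSSGWGQa")
  amb <- isobaricAlternatives(makh2, tolPpm = 5, precursorMz = 1092.51)
  l2 <- amb[amb$position == 2, ]
  q10 <- amb[amb$position == 10, ]
  expect_identical(l2$alternative, "I")
  expect_equal(l2$deltaDa, 0)
  expect_false(l2$resolvable)                 # Leu/Ile never mass-resolvable
  expect_equal(round(q10$deltaDa, 4), 0.0364) # Q -> K alternative
  expect_true(q10$resolvable)                 # 0.0364 > 5 ppm x 1092.51
  ## at ion-trap accuracy (0.3 Da ~ 275 ppm) Gln/Lys collapses too
  ambTrap <- isobaricAlternatives(makh2, tolPpm = 275, precursorMz = 1092.51)
  expect_false(ambTrap$resolvable[ambTrap$position == 10])

  ## octapeptide without Q/K reports only the Leu site
  amb2 <- isobaricAlternatives(parseAkhNotation("pELTFTPNWa"), tolPpm = 5)
  expect_identical(amb2$position, 2L)
})

test_that("MGF writing and reading round-trip spectra", {
  path <- withr::local_tempfile(fileext = ".mgf")
  s1 <- simulateCid(manse, seed = 3)
  s2 <- simulateCid(parseAkhNotation("pELTFTPNWa"), seed = 4)
  writeMgf(list(s1, s2), path, titles = c("manse", "peram"))
  back <- readMgf(path)
  expect_identical(names(back), c("manse", "peram"))
  expect_equal(precursorMz(back[[1]]), precursorMz(s1), tolerance = 1e-6)
  expect_equal(back[[1]]@mz, s1@mz, tolerance = 1e-6)
  expect_equal(back[[2]]@intensity, s2@intensity, tolerance = 1e-4)
})

test_that("annotation reports export as TSV", {
  s <- simulateCid(manse, seed = 11)
  a <- annotateSpectrum(s, manse)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotationTsv(a, path)
  tab <- read.delim(path)
  expect_identical(nrow(tab), nrow(a$matches))
  expect_true(all(c("mz", "intensity", "ion", "error_da") %in% names(tab)))
})
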