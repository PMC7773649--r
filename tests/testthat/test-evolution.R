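test_that("the built-in genetic code matches the Biostrings reference", {
  skip_if_not_installed("Biostrings")
  ref <- Biostrings::GENETIC_CODE
  code <- geneticCode()
  expect_identical(length(code), 64L)
  expect_identical(sum(code != "*"), 61L)
  expect_identical(unname(code[names(ref)]), as.character(ref))
})

test_that("minimal codon distances match a brute-force codon-pair oracle", {
  skip_if_not_installed("Biostrings")
  aas <- rownames(akhpep:::.RESIDUE_COMPOSITIONS)
  m <- minCodonDistanceMatrix()
  for (a in aas) for (b in aas)
    expect_identical(m[a, b], oracleMinCodonDistance(a, b),
                     label = paste(a, "->", b))
})

test_that("codon distance is a symmetric, bounded pre-metric", {
  m <- minCodonDistanceMatrix()
  expect_true(all(m == t(m)))
  expect_true(all(diag(m) == 0L))
  expect_true(all(m[upper.tri(m)] > 0L))
  expect_true(all(m <= 3L))
  ## the family's key steps
  expect_identical(minCodonDistance("N", "G"), 2L)
  expect_identical(minCodonDistance("S", "T"), 1L)
  expect_identical(minCodonDistance("S", "P"), 1L)
  expect_identical(minCodonDistance("L", "L"), 0L)
  expect_error(minCodonDistance("X", "G"), "unknown residue")
})

test_that("edit profiles reproduce the published pairwise relationships", {
  ## Manse-AKH vs Lacol-AKH: identical save one extra C-terminal Gly
  e <- peptideEditProfile("pELTFTSSWGa", "pELTFTSSWGGa")
  expect_identical(sum(e$perPosition), 0L)
  expect_identical(e$elongations, 1L)
  expect_identical(e$cost, 1L)

  ## Helze-HrTH vs Chipa-AKH: single Ser6 -> Thr6, one nucleotide
  e2 <- peptideEditProfile("pELTFSSGWGNa", "pELTFSTGWGNa")
  expect_identical(nrow(e2$changes), 1L)
  expect_identical(e2$changes$position, 6L)
  expect_identical(e2$changes$nt, 1L)

  ## Dircl-AKH-I is Manse-AKH-II minus the C-terminal Gln
  e3 <- peptideEditProfile("pELTFSSGWGa", "pELTFSSGWGQa")
  expect_identical(sum(e3$perPosition), 0L)
  expect_identical(e3$elongations, 1L)

  ## zero-cost self edge; symmetry of cost
  expect_identical(peptideEditProfile("pELTFTSSWGa", "pELTFTSSWGa")$cost, 0L)
  for (pair in list(c("pELTFTPNWa", "pELTFSSGWGQa"),
                    c("pELTFTSTWGa", "pELTFTSSWGGa"))) {
    expect_identical(peptideEditProfile(pair[1], pair[2])$cost,
                     peptideEditProfile(pair[2], pair[1])$cost)
  }
  expect_error(peptideEditProfile("pELTFTPNWa", "pELTFTSSWGa",
                                  alignment = "gapped"), "anchored")
})

test_that("the mutation graph links the published single-step neighbors", {
  mg <- buildMutationGraph(CONFIRMED_AKHS, maxEdgeCost = 1)
  g <- mg$graph
  ## Manse-AKH <-> Hipes-AKH-III: single Ser7/Thr7 nucleotide change
  expect_true(igraph::are_adjacent(g, "pELTFTSSWGa", "pELTFTSTWGa"))
  ## elongation edges
  expect_true(igraph::are_adjacent(g, "pELTFTSSWGa", "pELTFTSSWGGa"))
  expect_true(igraph::are_adjacent(g, "pELTFTPNWa", "pELTFTPNWGa"))
})

test_that("all confirmed AKHs interconnect at cost <= 2; Asn/Gly edges are flagged", {
  mg <- buildMutationGraph(CONFIRMED_AKHS, maxEdgeCost = 2,
                           allowHypothetical = TRUE, budget = 4)
  expect_true(mg$connected)
  expect_lte(length(mg$hypotheticals), 4L)
  e <- igraph::as_data_frame(mg$graph, what = "edges")
  expect_true(all(e$cost <= 2))
  ## every two-nucleotide substitution step is flagged, and only those
  twoNt <- grepl(":2nt", e$changes)
  expect_identical(e$flagged, twoNt)
  ## the Gln10/Asn10 exchange between the two decapeptide families is one
  qn <- e[(e$from == "pELTFSSGWGQa" & e$to == "pELTFSSGWGNa") |
            (e$from == "pELTFSSGWGNa" & e$to == "pELTFSSGWGQa"), ]
  expect_identical(nrow(qn), 1L)
  expect_true(qn$flagged)
  ## an Asn -> Gly step itself carries cost 2 and would be flagged
  ng <- peptideEditProfile("pELTFTPNWGa", "pELTFTPGWGa")
  expect_identical(ng$changes$nt[ng$changes$position == 7L], 2L)
  ## any proposed intermediates satisfy the grammar
  for (h in mg$hypotheticals)
    expect_true(grammarCheck(parseAkhNotation(h), akhGrammar("lepidopteran"))$pass)
})

test_that("degenerate graphs behave: single node, exhausted budget", {
  single <- buildMutationGraph("pELTFTSSWGa")
  expect_equal(igraph::vcount(single$graph), 1)
  expect_equal(igraph::ecount(single$graph), 0)
  expect_true(single$connected)

  ## distant pair, zero budget: partial graph with a component report
  far <- buildMutationGraph(c("pELTFTPNWa", "pELTFSSGWGQa"),
                            maxEdgeCost = 1, allowHypothetical = TRUE,
                            budget = 0)
  expect_false(far$connected)
  expect_equal(max(far$components), 2)
  expect_error(buildMutationGraph("pELTFTSSWGa", budget = -1), "budget")
})

test_that("graphs export as DOT and JSON", {
  skip_if_not_installed("jsonlite")
  mg <- buildMutationGraph(CONFIRMED_AKHS[c("Manse-AKH", "Lacol-AKH",
                                            "Hipes-AKH-III")],
                           maxEdgeCost = 2)
  dot <- withr::local_tempfile(fileext = ".dot")
  exportMutationGraph(mg, dot, "dot")
  expect_true(any(grepl("graph", readLines(dot), ignore.case = TRUE)))

  js <- withr::local_tempfile(fileext = ".json")
  exportMutationGraph(mg, js, "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(nrow(parsed$nodes), 3L)
  expect_true(all(c("cost", "changes") %in% names(parsed$edges)))
})
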