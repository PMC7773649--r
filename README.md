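# akhpep

Chemistry, tandem-MS annotation, cataloguing and molecular evolution of
adipokinetic hormones (AKHs) — the 8–10-residue insect neuropeptides with a
pyroglutamate (pGlu) N-terminus and an amidated C-terminus that mobilize
lipid and carbohydrate fuel from the fat body during flight. The package is
aimed at insect neuropeptide researchers and mass spectrometrists working
with this family, with the lepidopteran AKH complement as its packaged
reference dataset.

## What it does

* **Exact-mass chemistry** (`parseAkhNotation`, `ionMz`,
  `peptideComposition`): monoisotopic mass and CHNOS elemental-composition
  arithmetic for peptides in the compact AKH notation (`pELTFTSSWGa` =
  pGlu-Leu-Thr-Phe-Thr-Ser-Ser-Trp-Gly amide), with H, NH₄ and Na adducts.
  The neutral mass is Σ residue masses + NH₃ (amide) or H₂O (free acid);
  the protonated ion adds 1.007276 Da.
* **CID fragmentation and annotation** (`fragmentLadder`,
  `annotateSpectrum`, `matchScore`, `isobaricAlternatives`): theoretical
  b/y ladders with H₂O/NH₃ losses (bᵢ + yₙ₋ᵢ = MH⁺ + proton), greedy
  closest-match annotation with deterministic tie-breaks, and Leu/Ile
  (Δ = 0) / Gln/Lys (Δ = 0.0364 Da) ambiguity reporting at a stated mass
  accuracy.
* **Grammar-constrained identification** (`akhGrammar`,
  `enumerateCandidates`, `rankCandidates`,
  `detectProcessingIntermediate`): exhaustive enumeration of
  family-conforming sequences against a precursor mass, spectrum-based
  ranking, and mapping of free-acid Gly-(Lys/Arg)* precursor intermediates
  to their mature hormone.
* **The lepidopteran AKH catalog** (`loadCatalog`, `validateMasses`,
  `summarizeCatalog`, `queryCatalog`, `exportCatalog`): a packaged,
  machine-validated TSV covering 76 species and the 15 biochemically
  confirmed AKHs of Lepidoptera.
* **Codon-level evolution** (`minCodonDistance`, `peptideEditProfile`,
  `buildMutationGraph`): minimal point-mutation distances under the
  standard genetic code, C-terminal elongation events, and mutation
  networks with optional grammar-conforming hypothetical intermediates
  (DOT/JSON export).
* **Paired bioassay analysis** (`pairedAnalysis`, `assayTable`,
  `simulateAssay`): two-sided paired t-tests on pre/post (0 vs 90 min)
  hemolymph metabolite concentrations, plus a paired-design simulator.
* **Synthetic CID spectra** (`simulateCid`, `cidSimParams`, MGF I/O): an
  ion-trap-style spectrum generator (ion dropout, m/z jitter, chemical
  noise) so the identification pipeline is testable end to end.

A thin command-line wrapper is installed as `exec/akhpep`
(`akhpep mass pELTFTSSWGa --composition`, `akhpep catalog --summarize`,
`akhpep search --mz 988.4887`, ...).

## Worked example

```r
library(akhpep)

## Manse-AKH, the lepidopteran signature nonapeptide
manse <- parseAkhNotation("pELTFTSSWGa")
manse
#> AkhPeptide of length 9: pELTFTSSWGa  [(M+H)+ 1008.4785]

## HRMS discrimination of the near-isobaric Gln10/Lys10 decapeptides
hillFormula(peptideComposition(parseAkhNotation("pELTFSSGWGQa"), "H"))
#> [1] "C50H70N13O15"
round(ionMz(parseAkhNotation("pELTFSSGWGKa")), 4)
#> [1] 1092.5473

## Identify a simulated ion-trap CID spectrum of Peram-CAH-II
s  <- simulateCid(parseAkhNotation("pELTFTPNWa"), cidSimParams(), seed = 1)
cs <- enumerateCandidates(precursorMz(s), grammar = akhGrammar("lepidopteran"),
                          tol = 0.3)
rankCandidates(cs, s)$candidates[1, c("notation", "mz", "score")]
#>     notation       mz score
#> 1 pELTFTPNWa 988.4887    37

## The packaged catalog reproduces the published census
summarizeCatalog(loadCatalog())
#> AKH catalog: 76 species; 15 unique biochemically confirmed AKHs
#> (6 deca / 4 nona / 5 octa); max 5 AKHs in one species

## One evolutionary step: Helze-HrTH -> Chipa-AKH
peptideEditProfile("pELTFSSGWGNa", "pELTFSTGWGNa")
#> pELTFSSGWGNa <-> pELTFSTGWGNa: cost 1 (S6>T6:1nt)
```

The score 37 above is 36 matched fragment ions plus backbone coverage 1.0;
the winning notation collapses the mass-identical Leu/Ile alternative at
position 2 (reported via `nLeuIleSites`).

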