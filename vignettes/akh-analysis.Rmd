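---
title: "Identifying and comparing adipokinetic hormones: methods and design"
author: "akhpep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and comparing adipokinetic hormones: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akhpep)
```

## The biological problem

Adipokinetic hormones (AKHs) are short insect neuropeptides (8–10 residues)
released from the corpus cardiacum that mobilize lipid and carbohydrate fuel
from the fat body during flight. Mature AKHs carry two protective
post-translational modifications — a pyroglutamate (pGlu) ring at the
N-terminus and an amide at the C-terminus — which block exopeptidase
digestion and, for the analyst, change the elemental bookkeeping at both
ends of the chain. The family is structurally stereotyped: position 2 is
aliphatic or aromatic (always Leu in Lepidoptera), position 3 is Thr/Asn,
position 4 Phe/Tyr, position 5 Thr/Ser, position 8 Trp, position 9 Gly in
nona- and decapeptides, while positions 6, 7 and 10 vary freely. `akhpep`
turns this stereotypy into executable machinery: exact-mass chemistry,
CID fragment annotation, grammar-constrained identification, a validated
catalog of the lepidopteran AKH complement, codon-level evolutionary
arithmetic over the family, and the paired metabolite-mobilization bioassay
analysis used to characterize the peptides physiologically.

## Mass and composition arithmetic

A peptide's neutral monoisotopic mass is the sum of its water-free residue
masses plus the C-terminal group: NH~3~ for an amide, H~2~O for a free
acid. The pGlu ring is carried entirely by the pGlu residue composition
(C~5~H~5~NO~2~, 111.0320 Da); whether it cyclized from Gln or Glu is not
modeled, matching what mass spectrometry can observe. Atomic masses are the
standard monoisotopic values (H 1.0078250319, C 12 exactly, N
14.0030740052, O 15.9949146221, S 31.97207069) and the proton is 1.007276
Da; this set reproduces every published 4-decimal (M+H)^+^ value in the
packaged catalog to within rounding (max deviation ~5×10^-5^ Da).

```{r}
manse <- parseAkhNotation("pELTFTSSWGa")   # Manse-AKH
ionMz(manse, "H")
hillFormula(peptideComposition(parseAkhNotation("pELTFSSGWGQa"), "H"))
```

Two residue pairs are (near-)isobaric and drive the design in several
places. Leu/Ile are mass-identical at any resolution: the package never
claims to separate them by mass (the wet-lab evidence is LC co-elution,
represented only as a `resolvable = FALSE` flag). Gln/Lys differ by
−0.0364 Da, resolvable at high-resolution accuracy (a few ppm at ~1100 Da)
but not at ion-trap accuracy; `isobaricAlternatives()` applies exactly this
threshold arithmetic.

Positions are 1-based from the N-terminus throughout, matching the
convention in which "Ser^6^/Pro^6^ exchange" names the sixth residue.
Singly charged ions only: every interpreted AKH ion in the source data is
charge 1, and modeling higher charge states would add parameters nothing
here can test. Display rounding is 4 decimal places; all comparisons in
code use numeric tolerances, never string equality.

## Fragment ladders and annotation

CID of protonated peptides cleaves the backbone into N-terminal b-ions and
C-terminal y-ions; b~i~ + y~n−i~ always equals (M+H)^+^ plus one proton, a
conservation law the test-suite checks across every catalog peptide at
1×10^-5^ Da. Only b/y series with optional H~2~O/NH~3~ neutral losses are
generated — the series that carry the diagnostic information in ion-trap
spectra of AKHs — and a-ions and internal fragments are deliberately
excluded so that annotation and scoring are deterministic.

Annotation is greedy closest-match within a tolerance (default 0.3 Da for
ion-trap spectra, 5 ppm for orbitrap-class data), each observed peak
claimed by at most one theoretical ion. Conflicts resolve by smaller
absolute error, then y over b, then lower index: an arbitrary but fixed
tie-break, chosen so that re-running an annotation can never re-order it.
Coverage is the fraction of the n−1 backbone cleavage sites supported by at
least one matched ion. The match score is deliberately simple — matched-ion
count plus coverage — because the source assignments rest on m/z positions,
not intensities; intensities are generated for realism but never scored.

## Grammar-constrained identification

`enumerateCandidates()` formalizes the manual "assignment of a typical AKH
family member": enumerate the grammar's cartesian product over lengths
8–10, keep sequences within a precursor-mass window, and rank by match
score against the CID spectrum. Leu/Ile are collapsed to one symbol during
enumeration (they are mass-identical twins; reports carry a
`nLeuIleSites` count instead), keeping the lepidopteran search space at
~6×10^4^ sequences. The candidate cap (default 100,000) raises an explicit
overflow error rather than silently truncating. Precursor tolerances are
our own defaults — 0.005 Da for high-resolution enumeration, 0.3 Da when
ranking ion-trap spectra — as the source assignments never state a numeric
window.

```{r}
cs <- enumerateCandidates(988.4887, grammar = akhGrammar("lepidopteran"),
                          tol = 0.005)
head(cs$candidates, 3)
```

The free-acid processing rule inverts precursor biology: amidation is
donated by a Gly followed by basic residue(s), so a free-acid peptide
ending in Gly-(Lys/Arg)* is an incompletely processed precursor product,
and `detectProcessingIntermediate()` strips the basic tail and converts the
Gly into the amide to recover the mature hormone (the undecapeptide
Vanca-AKH maps to Manse-AKH this way).

## The packaged catalog

`inst/extdata/akh_catalog.tsv` transcribes the published distribution
table: 133 species×peptide rows over 76 species, with clade, superfamily,
family, peptide code name, canonical notation, printed (M+H)^+^, the
sequence as printed, an evidence class and a reference note. Three design
choices matter. First, each code name maps to one canonical sequence; four
table cells print letter-transposed sequences (e.g. `pELTFTSSGWa` for
Manse-AKH in one row), which are stored verbatim in `printed_sequence` and
verified by the validator to be composition-identical anagrams of the
canonical form. Second, evidence classes are `ms_confirmed` (directly or
previously sequenced by MS), `predicted_only` (accession/transcriptome
evidence only — including the two NOVEL placeholder decapeptides), and
`incompletely_processed` (the free-acid Vanca-AKH, excluded from the
15-peptide tally). Third, "Helze-AKH" and "Manse-AKH-I" are recorded under
their standard names (Helze-HrTH, Manse-AKH) with the printed alias noted
in the reference field. With these choices the summary reproduces the
published census exactly: 76 species, 15 unique confirmed AKHs splitting
6 deca / 4 nona / 5 octa, at most 5 AKHs in one species (*Hippotion*).

```{r}
summarizeCatalog(loadCatalog())
```

## Codon-level evolution

The family's evolutionary arithmetic counts nucleotide point mutations:
`minCodonDistance()` is the minimum Hamming distance over all codon pairs
encoding two residues under the standard nuclear code (no codon-usage
weighting — no usage data exist for these loci, and minimizing over
synonymous codons is the assumption implicit in "point mutation"
reasoning). Chain elongation is typed as its own event costing 1 per added
C-terminal residue, since the family grows strictly at the C-terminus.
Alignment is therefore N-anchored with C-terminal overhang only; gapped
alignment is refused rather than approximated. `buildMutationGraph()`
connects peptides whose total cost (substitution nucleotides + elongations)
is within a budget; edges needing ≥2 nucleotides at one position (the
Asn/Gly and Gln/Asn exchanges) are flagged, mirroring the special status of
two-nucleotide steps in the family's proposed evolutionary scheme. A
bounded, lexicographically ordered search can propose grammar-conforming
hypothetical intermediates (single-substitution neighbors of observed
peptides) to bridge disconnected components; no Steiner-tree optimality is
claimed. In practice the 15 confirmed lepidopteran AKHs are already
mutually reachable at edge cost ≤ 2 with zero intermediates.

## The paired bioassay

The physiological readout is a paired design: hemolymph metabolite
concentration in the same animal before injection and 90 min after.
`pairedAnalysis()` applies the two-sided paired t-test
(t = mean(d)/(sd(d)/√n), n−1 df) with sample SDs; two-sided because the
published tables report non-significant *negative* differences for water
controls, which a one-sided test could not produce. A degenerate group with
exactly constant differences is reported with t = ±Inf and p at the
smallest positive double rather than an error. The raw per-animal data
behind the published tables are not available, so those printed differences
are not recomputable; `simulateAssay()` instead emulates the design — a
zero-truncated Gaussian baseline, an additive treatment effect, and
within-animal Gaussian noise — so that calibration (type-I rate 0.05 under
the null) and effect recovery (bias within Monte-Carlo error) are testable.
Baseline moments for simulations use the published resting-lipid values
(22.22 ± 6.24 µg/µl); the within-animal noise SD (2.5–3) is set to the
scale of the published difference SDs.

## The spectrum simulator, and what passing tests mean

No raw spectra are deposited with the source data, so the identification
pipeline is validated end-to-end on synthetic ion-trap CID spectra: the
theoretical b/y ± loss ladder with 20% per-ion dropout, 0.05 Da Gaussian
m/z jitter, lognormal intensities, and 20 uniform chemical-noise peaks.
Under those defaults the true peptide (or its Leu/Ile twin) ranks first in
well over 90% of simulated spectra across the 15 confirmed AKHs, and the
identification rate degrades monotonically with dropout and jitter. The
simulator reproduces the *evidence class* of real ion-trap data, not its
physics: it does not model intensity structure (proline effects, preferred
cleavages), correlated noise, co-isolated precursors, or LC behavior.
Passing the round-trip therefore shows the search and scorer are correct
and robust to centroid-level noise — not that real-spectrum identification
at these rates is guaranteed.

## Problem sizes and numerical choices

The test-suite runs the identification round trip at 50 spectra per
peptide (750 total), calibration at 2,000 null replicates, and effect
recovery at 1,000 replicates — sizes at which the Monte-Carlo error of each
checked quantity is comfortably inside its acceptance band. All simulation
seeds are fixed and derived deterministically; the simulator restores the
caller's RNG state so package randomness never leaks into user code.
Equality of masses is always tested against tolerances (1×10^-5^ Da for
internal consistency, 5×10^-4^ Da against printed 4-d.p. values); rounding
for display is round-half-even.

## Known limitations

* Charge states > 1, isotope patterns and PTMs other than pGlu/amide
  (hydroxyproline, Trp modifications, sulfation, ...) are out of scope; no
  catalog peptide requires them.
* Leu/Ile assignments rely on external evidence by construction; the
  package reports the ambiguity rather than resolving it.
* The mutation network proposes *candidate* intermediates; it does not
  reconstruct ancestral states or claim the historically realized path.
* The catalog is a snapshot transcription; post-publication additions to
  the lepidopteran AKH complement are not tracked.
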