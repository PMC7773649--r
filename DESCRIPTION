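Package: akhpep
Title: Chemistry, Tandem-MS Annotation, Cataloguing and Molecular Evolution
    of Adipokinetic Hormones
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the adipokinetic hormone (AKH) neuropeptide family of
    insects, centred on Lepidoptera. Implements exact monoisotopic mass and
    elemental-composition arithmetic for peptides with pyroglutamate
    N-termini and amidated or free-acid C-termini; theoretical b/y
    collision-induced dissociation (CID) fragment-ion ladders with water and
    ammonia neutral losses; spectrum annotation, match scoring and isobaric
    Leu/Ile and Gln/Lys ambiguity reporting; grammar-constrained candidate
    enumeration against a precursor mass; a packaged, machine-validated
    catalog of the lepidopteran AKH complement with queries and summaries;
    codon-level minimal point-mutation networks over the peptide family; a
    paired pre/post metabolite-mobilization bioassay analysis; and synthetic
    generators for CID spectra and paired assay data so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, igraph
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr, Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
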