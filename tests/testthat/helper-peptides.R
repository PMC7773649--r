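## Shared fixtures: the 15 biochemically confirmed lepidopteran AKHs with
## their published code names and printed (M+H)+ values, plus a few
## ancillary sequences.  Used across module tests; the packaged catalog is
## the authoritative copy and is cross-checked against this list.

CONFIRMED_AKHS <- c(
  "Peram-CAH-II" = "pELTFTPNWa",
  "Piebr-AKH"    = "pELTFSSGWa",
  "Dircl-AKH-II" = "pELTFSTGWa",
  "Hipes-AKH-I"  = "pELTFTSSWa",
  "Hipes-AKH-II" = "pELTFTSTWa",
  "Manse-AKH"    = "pELTFTSSWGa",
  "Triin-AKH"    = "pELTFTPNWGa",
  "Dircl-AKH-I"  = "pELTFSSGWGa",
  "Hipes-AKH-III" = "pELTFTSTWGa",
  "Lacol-AKH"    = "pELTFTSSWGGa",
  "Manse-AKH-II" = "pELTFSSGWGQa",
  "Helze-HrTH"   = "pELTFSSGWGNa",
  "Chipa-AKH"    = "pELTFSTGWGNa",
  "Antya-AKH"    = "pELTFSPGWGQa",
  "Bommo-AKH"    = "pELTFTPGWGQa"
)

PRINTED_MH <- c(
  "Peram-CAH-II" = 988.4887, "Piebr-AKH" = 907.4308,
  "Dircl-AKH-II" = 921.4465, "Hipes-AKH-I" = 951.4571,
  "Hipes-AKH-II" = 965.4727, "Manse-AKH" = 1008.4785,
  "Triin-AKH" = 1045.5102, "Dircl-AKH-I" = 964.4523,
  "Hipes-AKH-III" = 1022.4942, "Lacol-AKH" = 1065.5000,
  "Manse-AKH-II" = 1092.5109, "Helze-HrTH" = 1078.4952,
  "Chipa-AKH" = 1092.5109, "Antya-AKH" = 1102.5316,
  "Bommo-AKH" = 1116.5473
)

VANCA <- "pELTFTSSWGGK-OH"   # incompletely processed Manse-AKH precursor form

## Independent brute-force codon-distance oracle, deliberately built on the
## Biostrings genetic-code table rather than the package's own.
oracleMinCodonDistance <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  ca <- names(code)[code == a]
  cb <- names(code)[code == b]
  best <- 3L
  for (x in ca) for (y in cb) {
    d <- sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    if (d < best) best <- d
  }
  best
}
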