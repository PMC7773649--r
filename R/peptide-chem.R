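## Peptide-level mass and composition arithmetic.
##
## The neutral peptide is the sum of its water-free residue compositions plus
## the C-terminal group: NH3 for an amide, H2O for a free acid.  The
## pyroglutamate ring is carried entirely by the pGlu residue composition
## (C5H5NO2), so no further N-terminal correction is needed.

## Internal: residue codes with pE substituted for a pyroglutamate position 1.
.effectiveResidues <- function(p) {
  res <- residues(p)
  if (identical(nTerm(p), "pyroglutamate")) res[1L] <- "pE"
  res
}

#' Neutral or ionized elemental composition of a peptide
#'
#' Sums the residue compositions, adds NH3 (amide) or H2O (free acid) for the
#' C-terminus, and optionally the composition of an adduct.  Sodium is not a
#' CHNOS element; for the Na-containing adducts only the CHNOS part is
#' reported (the printed AKH ion formulas are all protonated species).
#'
#' @param p An [AkhPeptide-class].
#' @param ionizedBy `NULL` for the neutral molecule, or an adduct name among
#'   `"H"`, `"NH4"`, `"Na"`, `"NH4+Na"`.
#' @return Named integer vector of element counts (C, H, N, O, S).
#' @examples
#' hillFormula(peptideComposition(parseAkhNotation("pELTFSSGWGQa"), "H"))
#' # "C50H70N13O15" -- Manse-AKH-II (M+H)+
#' @export
peptideComposition <- function(p, ionizedBy = NULL) {
  stopifnot(is(p, "AkhPeptide"))
  res <- .effectiveResidues(p)
  comp <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (r in res) comp <- comp + residueComposition(r)
  comp <- comp + if (identical(cTerm(p), "amide")) .NH3 else .H2O
  if (!is.null(ionizedBy)) {
    if (!ionizedBy %in% names(.ADDUCT_COMPOSITIONS))
      stop("unknown adduct: '", ionizedBy, "'")
    comp <- comp + .ADDUCT_COMPOSITIONS[[ionizedBy]]
  }
  comp
}

#' Neutral monoisotopic mass of a peptide
#'
#' @param p An [AkhPeptide-class].
#' @return Mass in Da.
#' @export
neutralMass <- function(p) {
  stopifnot(is(p, "AkhPeptide"))
  terminal <- if (identical(cTerm(p), "amide")) .MASS_NH3 else .MASS_H2O
  sum(.RESIDUE_MASSES[.effectiveResidues(p)]) + terminal
}

#' Singly charged ion m/z of a peptide
#'
#' Neutral monoisotopic mass plus the adduct shift: +1.007276 for H,
#' +18.033823 for NH4, +22.989218 for Na.  All AKH ions handled here are
#' singly charged.  Values are returned at full precision; 4 decimal places
#' is the conventional display rounding.
#'
#' @param p An [AkhPeptide-class].
#' @param adduct Adduct name, default `"H"`.
#' @return m/z in Da (charge 1).
#' @examples
#' ionMz(parseAkhNotation("pELTFTSSWGa"))           # 1008.4785, Manse-AKH
#' ionMz(parseAkhNotation("pELTFTPNWa"))            # 988.4887,  Peram-CAH-II
#' @export
ionMz <- function(p, adduct = "H") {
  if (!adduct %in% names(.ADDUCT_SHIFTS))
    stop("unknown adduct: '", adduct, "'")
  neutralMass(p) + .ADDUCT_SHIFTS[[adduct]]
}

#' Signed mass error in parts per million
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z; must be positive.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppmError <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}
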