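## Atomic-level constants used throughout the package.
##
## Monoisotopic atomic masses follow the standard reference table; the proton
## mass (1.007276 Da) is the m/z shift of protonation at charge 1.  These five
## elements cover the 20 proteinogenic residues and all terminal groups and
## adducts handled here.

.ELEMENTS <- c(
  C = 12,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

.PROTON <- 1.007276

## Residue (water-free) elemental compositions of the 20 standard amino acids,
## rows = element counts in Hill-order columns C, H, N, O, S.
.RESIDUE_COMPOSITIONS <- local({
  m <- rbind(
    A = c(3, 5, 1, 1, 0),
    R = c(6, 12, 4, 1, 0),
    N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),
    C = c(3, 5, 1, 1, 1),
    E = c(5, 7, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),
    G = c(2, 3, 1, 1, 0),
    H = c(6, 7, 3, 1, 0),
    I = c(6, 11, 1, 1, 0),
    L = c(6, 11, 1, 1, 0),
    K = c(6, 12, 2, 1, 0),
    M = c(5, 9, 1, 1, 1),
    F = c(9, 9, 1, 1, 0),
    P = c(5, 7, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),
    T = c(4, 7, 1, 2, 0),
    W = c(11, 10, 2, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    V = c(5, 9, 1, 1, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
})

## Pyroglutamate: cyclized N-terminal Glu/Gln, residue composition C5H5NO2.
## Modeled as its own residue symbol "pE"; whether it arose from Gln or Glu
## is not represented.
.PGLU_COMPOSITION <- c(C = 5, H = 5, N = 1, O = 2, S = 0)

.H2O <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
.NH3 <- c(C = 0, H = 3, N = 1, O = 0, S = 0)

.MASS_H2O <- 18.010565  # neutral water,  also the b-ion H2O loss
.MASS_NH3 <- 17.026549  # neutral ammonia, also the y-ion NH3 loss

## Singly charged adduct m/z shifts relative to the neutral monoisotopic mass.
## NH4+Na (seen as a minor corroborating species in ion-trap spectra) is taken
## as simultaneous ammonium and sodium attachment with loss of one proton so
## the species stays singly charged.
.ADDUCT_SHIFTS <- c(
  H      = 1.007276,
  NH4    = 18.033823,
  Na     = 22.989218,
  `NH4+Na` = 18.033823 + 22.989218 - 1.007276
)

.ADDUCT_COMPOSITIONS <- list(
  H      = c(C = 0, H = 1, N = 0, O = 0, S = 0),
  NH4    = c(C = 0, H = 4, N = 1, O = 0, S = 0),
  Na     = c(C = 0, H = 0, N = 0, O = 0, S = 0),  # Na tracked outside CHNOS
  `NH4+Na` = c(C = 0, H = 3, N = 1, O = 0, S = 0)
)

#' Monoisotopic mass of an elemental composition
#'
#' @param composition Named integer vector of element counts; names must be a
#'   subset of C, H, N, O, S.
#' @return Monoisotopic mass in Da.
#' @examples
#' compositionMass(c(C = 2, H = 3, N = 1, O = 1)) # glycine residue
#' @export
compositionMass <- function(composition) {
  stopifnot(is.numeric(composition), !is.null(names(composition)))
  unknown <- setdiff(names(composition), names(.ELEMENTS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(composition < 0)) stop("element counts must be non-negative")
  sum(composition * .ELEMENTS[names(composition)])
}

#' Format an elemental composition in Hill order
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; elements
#' with zero count are omitted.
#'
#' @inheritParams compositionMass
#' @return A single string such as `"C50H70N13O15"`.
#' @export
hillFormula <- function(composition) {
  order <- c("C", "H", setdiff(sort(names(.ELEMENTS)), c("C", "H")))
  parts <- vapply(order, function(el) {
    n <- if (el %in% names(composition)) composition[[el]] else 0
    if (n == 0) "" else if (n == 1) el else paste0(el, n)
  }, character(1))
  paste0(parts, collapse = "")
}

#' Monoisotopic residue mass
#'
#' Water-free residue mass of a standard amino acid, or of pyroglutamate via
#' the code `"pE"`.  The near-isobaric pair Gln/Lys differs by exactly the
#' CH2 vs NH2+H2 exchange: `residueMass("Q") - residueMass("K")` is
#' -0.0364 Da, the margin used to discriminate the two residues by
#' high-resolution MS.
#'
#' @param code One-letter residue code (or `"pE"`).
#' @return Monoisotopic mass in Da.
#' @examples
#' residueMass("Q") # 128.0586
#' residueMass("K") # 128.0950
#' @export
residueMass <- function(code) {
  compositionMass(residueComposition(code))
}

#' Elemental composition of a residue
#'
#' @inheritParams residueMass
#' @return Named integer vector over C, H, N, O, S.
#' @export
residueComposition <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  if (code == "pE") return(.PGLU_COMPOSITION)
  if (!code %in% rownames(.RESIDUE_COMPOSITIONS))
    stop("unknown residue code: '", code, "'")
  .RESIDUE_COMPOSITIONS[code, ]
}

## Internal: residue mass lookup vector including pE, for vectorized sums.
.RESIDUE_MASSES <- local({
  masses <- apply(.RESIDUE_COMPOSITIONS, 1L, function(x) sum(x * .ELEMENTS))
  c(masses, pE = sum(.PGLU_COMPOSITION * .ELEMENTS))
})
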