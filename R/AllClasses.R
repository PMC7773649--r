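#' @import methods
NULL

#' AkhPeptide: an AKH-style peptide with modified termini
#'
#' Central chemical object of the package: an ordered run of one-letter
#' residue codes (position 1 = N-terminus) together with the state of both
#' termini.  Mature AKHs carry a pyroglutamate (pGlu) N-terminus and an
#' amidated C-terminus; precursor-processing intermediates end in a free
#' carboxylic acid.
#'
#' @slot residues character vector of one-letter codes, position 1 first.
#'   When `nTerm == "pyroglutamate"` residue 1 is `"E"` (written `pE` in the
#'   compact notation; the cyclized ring is accounted for in the mass
#'   arithmetic, not in the letter).
#' @slot nTerm `"pyroglutamate"` or `"free"`.
#' @slot cTerm `"amide"` or `"free_acid"`.
#'
#' @seealso [parseAkhNotation()], [ionMz()], [fragmentLadder()]
#' @export
setClass("AkhPeptide",
  representation(
    residues = "character",
    nTerm = "character",
    cTerm = "character"
  ),
  prototype(nTerm = "pyroglutamate", cTerm = "amide")
)

setValidity("AkhPeptide", function(object) {
  msg <- character(0)
  if (length(object@residues) < 1L)
    msg <- c(msg, "peptide must contain at least one residue")
  bad <- setdiff(object@residues, rownames(.RESIDUE_COMPOSITIONS))
  if (length(bad))
    msg <- c(msg, paste0("unknown residue code(s): ", paste(bad, collapse = ", ")))
  if (!object@nTerm %in% c("pyroglutamate", "free"))
    msg <- c(msg, "nTerm must be 'pyroglutamate' or 'free'")
  if (!object@cTerm %in% c("amide", "free_acid"))
    msg <- c(msg, "cTerm must be 'amide' or 'free_acid'")
  if (identical(object@nTerm, "pyroglutamate") &&
      length(object@residues) >= 1L && object@residues[1L] != "E")
    msg <- c(msg, "pyroglutamate N-terminus requires residue 1 to be E")
  if (length(msg)) msg else TRUE
})

#' Construct an AkhPeptide
#'
#' @param residues Character vector of one-letter codes (or a single string,
#'   which is split into characters).
#' @param nTerm `"pyroglutamate"` (default) or `"free"`.
#' @param cTerm `"amide"` (default) or `"free_acid"`.
#' @return An [AkhPeptide-class] object.
#' @examples
#' AkhPeptide("ELTFTSSWG")              # Manse-AKH
#' @export
AkhPeptide <- function(residues, nTerm = "pyroglutamate", cTerm = "amide") {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "", fixed = TRUE)[[1L]]
  new("AkhPeptide", residues = residues, nTerm = nTerm, cTerm = cTerm)
}

#' @describeIn AkhPeptide-class residue vector accessor
#' @param x,object An `AkhPeptide`.
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname AkhPeptide-class
#' @export
setMethod("residues", "AkhPeptide", function(x) x@residues)

#' @rdname AkhPeptide-class
#' @export
setGeneric("nTerm", function(x) standardGeneric("nTerm"))
#' @rdname AkhPeptide-class
#' @export
setMethod("nTerm", "AkhPeptide", function(x) x@nTerm)

#' @rdname AkhPeptide-class
#' @export
setGeneric("cTerm", function(x) standardGeneric("cTerm"))
#' @rdname AkhPeptide-class
#' @export
setMethod("cTerm", "AkhPeptide", function(x) x@cTerm)

#' @rdname AkhPeptide-class
#' @export
setMethod("length", "AkhPeptide", function(x) length(x@residues))

#' @rdname AkhPeptide-class
#' @export
setMethod("show", "AkhPeptide", function(object) {
  cat("AkhPeptide of length ", length(object@residues), ": ",
      formatAkhNotation(object), "  [(M+H)+ ",
      sprintf("%.4f", ionMz(object, "H")), "]\n", sep = "")
})

#' CidSpectrum: a centroided CID tandem-MS peak list
#'
#' Holds the MS evidence for one precursor: the precursor m/z and a list of
#' (m/z, intensity) centroids, plus a resolution class that picks sensible
#' default tolerances (`"ion_trap"`: 0.3 Da; `"orbitrap"`: 5 ppm).
#'
#' @slot precursorMz Precursor m/z (charge 1 assumed).
#' @slot mz Numeric vector of peak m/z values, sorted ascending.
#' @slot intensity Non-negative numeric vector, parallel to `mz`.
#' @slot resolutionClass `"ion_trap"` or `"orbitrap"`.
#' @export
setClass("CidSpectrum",
  representation(
    precursorMz = "numeric",
    mz = "numeric",
    intensity = "numeric",
    resolutionClass = "character"
  ),
  prototype(resolutionClass = "ion_trap")
)

setValidity("CidSpectrum", function(object) {
  msg <- character(0)
  if (length(object@precursorMz) != 1L || object@precursorMz <= 0)
    msg <- c(msg, "precursorMz must be a single positive number")
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (is.unsorted(object@mz))
    msg <- c(msg, "peaks must be sorted ascending by m/z")
  if (length(object@intensity) && any(object@intensity < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (!object@resolutionClass %in% c("ion_trap", "orbitrap"))
    msg <- c(msg, "resolutionClass must be 'ion_trap' or 'orbitrap'")
  if (length(msg)) msg else TRUE
})

#' Construct a CidSpectrum
#'
#' Peaks are sorted by m/z on construction, so downstream code may rely on
#' ascending order.
#'
#' @param precursorMz Precursor m/z (Da, charge 1).
#' @param mz,intensity Parallel numeric vectors of peak centroids.
#' @param resolutionClass `"ion_trap"` (default) or `"orbitrap"`.
#' @return A [CidSpectrum-class] object.
#' @export
CidSpectrum <- function(precursorMz, mz = numeric(0), intensity = numeric(0),
                        resolutionClass = "ion_trap") {
  o <- order(mz)
  new("CidSpectrum", precursorMz = as.numeric(precursorMz),
      mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o],
      resolutionClass = resolutionClass)
}

#' @rdname CidSpectrum-class
#' @param x,object A `CidSpectrum`.
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))
#' @rdname CidSpectrum-class
#' @export
setMethod("precursorMz", "CidSpectrum", function(x) x@precursorMz)

#' @rdname CidSpectrum-class
#' @export
setGeneric("peakTable", function(x) standardGeneric("peakTable"))
#' @rdname CidSpectrum-class
#' @export
setMethod("peakTable", "CidSpectrum", function(x)
  data.frame(mz = x@mz, intensity = x@intensity))

#' @rdname CidSpectrum-class
#' @export
setMethod("length", "CidSpectrum", function(x) length(x@mz))

#' @rdname CidSpectrum-class
#' @export
setMethod("show", "CidSpectrum", function(object) {
  cat("CidSpectrum: precursor m/z ", sprintf("%.4f", object@precursorMz),
      ", ", length(object@mz), " peaks (", object@resolutionClass, ")\n",
      sep = "")
})
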