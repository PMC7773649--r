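## Synthetic CID spectrum generator.
##
## No raw spectra accompany the AKH survey data, so end-to-end testing of
## annotation and candidate ranking runs on simulated ion-trap CID spectra:
## the theoretical b/y ladder with per-ion dropout, Gaussian m/z jitter,
## lognormal intensities, and uniform chemical-noise peaks.

#' Simulation parameters for synthetic CID spectra
#'
#' Defaults emulate an ion-trap (LTQ-class) CID spectrum: every b/y ion and
#' its H2O/NH3 satellites with 20% random dropout, 0.05 Da m/z jitter, and
#' 20 chemical-noise peaks.  The `orbitrap` preset tightens jitter to
#' ppm scale.
#'
#' @param losses Neutral losses to emit alongside the plain b/y series.
#' @param dropout Per-ion probability of not being observed, in `[0, 1]`.
#' @param jitterSd Gaussian m/z jitter SD in Da (>= 0).
#' @param baseIntensity Median intensity of backbone ions.
#' @param intensitySpread SD of the lognormal intensity spread (log scale).
#' @param noisePeaks Number of uniform chemical-noise peaks.
#' @param noiseMzRange Length-2 m/z range for noise peaks; `NULL` means from
#'   100 Da up to the precursor.
#' @param resolutionClass `"ion_trap"` or `"orbitrap"` (stamps the spectrum
#'   and, for orbitrap, rescales jitter to 5 ppm at 1000 Da unless jitterSd
#'   is given explicitly).
#' @return A list of class `"cidSimParams"`.
#' @export
cidSimParams <- function(losses = c("none", "H2O", "NH3"),
                         dropout = 0.2, jitterSd = 0.05,
                         baseIntensity = 100, intensitySpread = 0.6,
                         noisePeaks = 20L, noiseMzRange = NULL,
                         resolutionClass = "ion_trap") {
  if (dropout < 0 || dropout > 1) stop("dropout must be in [0, 1]")
  if (jitterSd < 0) stop("jitterSd must be >= 0")
  if (noisePeaks < 0) stop("noisePeaks must be >= 0")
  structure(list(losses = losses, dropout = dropout, jitterSd = jitterSd,
                 baseIntensity = baseIntensity,
                 intensitySpread = intensitySpread,
                 noisePeaks = as.integer(noisePeaks),
                 noiseMzRange = noiseMzRange,
                 resolutionClass = resolutionClass),
            class = "cidSimParams")
}

#' Simulate a CID spectrum of a peptide
#'
#' Builds the theoretical fragment ladder, keeps each ion with probability
#' `1 - dropout`, jitters the surviving m/z values, draws lognormal
#' intensities (neutral-loss satellites at one third the backbone base
#' intensity), and adds uniform chemical-noise peaks.  The precursor m/z is
#' the theoretical (M+H)+ plus one jitter draw.  Fully reproducible given
#' `seed`.
#'
#' @param p An [AkhPeptide-class].
#' @param params A [cidSimParams()] list.
#' @param seed Integer seed fixing the full output.
#' @return A [CidSpectrum-class].
#' @examples
#' simulateCid(parseAkhNotation("pELTFTSSWGa"), seed = 7)
#' @export
simulateCid <- function(p, params = cidSimParams(), seed = 1L) {
  stopifnot(is(p, "AkhPeptide"), inherits(params, "cidSimParams"))
  ladder <- fragmentLadder(p, losses = params$losses)
  withr_seed <- .withSeed(seed)
  on.exit(withr_seed())

  keep <- stats::runif(nrow(ladder)) >= params$dropout
  mz <- ladder$mz[keep] + stats::rnorm(sum(keep), 0, params$jitterSd)
  base <- ifelse(ladder$loss[keep] == "none",
                 params$baseIntensity, params$baseIntensity / 3)
  intensity <- base * stats::rlnorm(sum(keep), 0, params$intensitySpread)

  precursor <- ionMz(p, "H") + stats::rnorm(1L, 0, params$jitterSd)
  rng <- params$noiseMzRange
  if (is.null(rng)) rng <- c(100, precursor)
  if (params$noisePeaks > 0L) {
    nmz <- stats::runif(params$noisePeaks, rng[1L], rng[2L])
    nint <- params$baseIntensity / 5 *
      stats::rlnorm(params$noisePeaks, 0, params$intensitySpread)
    mz <- c(mz, nmz)
    intensity <- c(intensity, nint)
  }
  CidSpectrum(precursor, mz, intensity, params$resolutionClass)
}

## Internal: set the RNG state locally and restore on exit.
.withSeed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
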