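## Theoretical CID fragment-ion ladders and spectrum annotation.
##
## Only singly charged b- and y-ions with optional H2O / NH3 neutral losses
## are modeled: these are the series that carry the diagnostic information in
## ion-trap CID spectra of AKH peptides.  a-ions and internal fragments are
## deliberately excluded to keep annotation deterministic.

#' Theoretical b/y fragment-ion ladder
#'
#' For a peptide of length n, b_i covers residues 1..i (including the
#' pyroglutamate N-terminus) and y_j covers residues (n-j+1)..n plus the
#' C-terminal group (NH3 for an amide, H2O for a free acid); both carry one
#' proton.  Neutral losses subtract 18.010565 Da (H2O) or 17.026549 Da (NH3).
#'
#' @param p An [AkhPeptide-class] of length >= 2.
#' @param series Character subset of `c("b", "y")`.
#' @param losses Character subset of `c("none", "H2O", "NH3")`.
#' @return A data.frame sorted by m/z with columns `series`, `index`,
#'   `loss`, `label` (e.g. `"b3-H2O"`), `mz`.
#' @examples
#' fragmentLadder(parseAkhNotation("pELTFTSSWGa"))
#' @export
fragmentLadder <- function(p, series = c("b", "y"),
                           losses = "none") {
  stopifnot(is(p, "AkhPeptide"))
  n <- length(p)
  if (n < 2L) stop("fragment ladder requires a peptide of length >= 2")
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  losses <- match.arg(losses, c("none", "H2O", "NH3"), several.ok = TRUE)

  masses <- .RESIDUE_MASSES[.effectiveResidues(p)]
  idx <- seq_len(n - 1L)
  base <- list()
  if ("b" %in% series)
    base$b <- cumsum(masses)[idx] + .PROTON
  if ("y" %in% series) {
    terminal <- if (identical(cTerm(p), "amide")) .MASS_NH3 else .MASS_H2O
    base$y <- cumsum(rev(masses))[idx] + terminal + .PROTON
  }
  lossShift <- c(none = 0, H2O = .MASS_H2O, NH3 = .MASS_NH3)

  rows <- do.call(rbind, lapply(names(base), function(s) {
    do.call(rbind, lapply(losses, function(l) {
      data.frame(series = s, index = idx, loss = l,
                 mz = base[[s]] - lossShift[[l]])
    }))
  }))
  rows$label <- paste0(rows$series, rows$index,
                       ifelse(rows$loss == "none", "", paste0("-", rows$loss)))
  rows <- rows[order(rows$mz), c("series", "index", "loss", "label", "mz")]
  rownames(rows) <- NULL
  rows
}

## Internal: resolve a tolerance spec into absolute Da at a given m/z.
## tol may be a number (Da) or a string "0.3Da" / "5ppm".
.tolDa <- function(tol, at) {
  if (is.character(tol)) {
    if (grepl("ppm$", tol)) {
      v <- as.numeric(sub("ppm$", "", tol))
      return(v * at * 1e-6)
    }
    tol <- as.numeric(sub("Da$", "", tol))
  }
  rep_len(tol, length(at))
}

#' Annotate a spectrum against a peptide's theoretical ladder
#'
#' Greedy closest-match assignment: theoretical ions are matched to observed
#' peaks within tolerance, each peak claimed by at most one ion.  Conflicts
#' are resolved by smaller absolute mass error, then y before b, then lower
#' index (a fixed, documented tie-break so annotation is reproducible).
#' Coverage per series is the fraction of the n-1 backbone cleavage sites
#' supported by at least one matched ion of that series; overall coverage
#' counts support from either series.
#'
#' @param s A [CidSpectrum-class].
#' @param p An [AkhPeptide-class].
#' @param tol Match tolerance: numeric Da, or a string like `"0.3Da"` or
#'   `"5ppm"`.  Default 0.3 Da (ion-trap CID).
#' @param losses Neutral losses to include, as in [fragmentLadder()].
#' @return A list of class `"akhAnnotation"` with elements `matches` (a
#'   data.frame: peak index, peak m/z, intensity, ion label, series, index,
#'   theoretical m/z, error in Da), `coverage` (overall), `coverageBySeries`,
#'   `unmatchedPeaks`, and `nTheoretical`.
#' @export
annotateSpectrum <- function(s, p, tol = 0.3,
                             losses = c("none", "H2O", "NH3")) {
  stopifnot(is(s, "CidSpectrum"), is(p, "AkhPeptide"))
  if (is.numeric(tol) && tol <= 0) stop("tolerance must be positive")
  ladder <- fragmentLadder(p, losses = losses)
  n <- length(p)
  mz <- s@mz

  empty <- data.frame(peak = integer(0), peakMz = numeric(0),
                      intensity = numeric(0), label = character(0),
                      series = character(0), index = integer(0),
                      theoreticalMz = numeric(0), errorDa = numeric(0))
  if (!length(mz)) {
    out <- list(matches = empty, coverage = 0,
                coverageBySeries = c(b = 0, y = 0),
                unmatchedPeaks = 0L, nTheoretical = nrow(ladder))
    class(out) <- "akhAnnotation"
    return(out)
  }

  ## nearest observed peak for each theoretical ion
  pos <- findInterval(ladder$mz, mz)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(mz))
  dlo <- abs(mz[lo] - ladder$mz)
  dhi <- abs(mz[hi] - ladder$mz)
  nearest <- ifelse(dhi < dlo, hi, lo)
  err <- mz[nearest] - ladder$mz
  within <- abs(err) <= .tolDa(tol, ladder$mz)

  cand <- ladder[within, , drop = FALSE]
  cand$peak <- nearest[within]
  cand$errorDa <- err[within]
  ## deterministic conflict resolution: |error|, then y before b, then index
  ord <- order(abs(cand$errorDa),
               match(cand$series, c("y", "b")),
               cand$index)
  cand <- cand[ord, , drop = FALSE]
  keep <- !duplicated(cand$peak)
  cand <- cand[keep, , drop = FALSE]

  matches <- data.frame(
    peak = cand$peak, peakMz = mz[cand$peak],
    intensity = s@intensity[cand$peak],
    label = cand$label, series = cand$series, index = cand$index,
    theoreticalMz = cand$mz, errorDa = cand$errorDa
  )
  matches <- matches[order(matches$peakMz), , drop = FALSE]
  rownames(matches) <- NULL

  ## cleavage site i (1..n-1) is supported by b_i or y_{n-i}
  siteOf <- ifelse(matches$series == "b", matches$index, n - matches$index)
  coverage <- length(unique(siteOf)) / (n - 1L)
  covB <- length(unique(matches$index[matches$series == "b"])) / (n - 1L)
  covY <- length(unique(matches$index[matches$series == "y"])) / (n - 1L)

  out <- list(matches = matches, coverage = coverage,
              coverageBySeries = c(b = covB, y = covY),
              unmatchedPeaks = length(mz) - nrow(matches),
              nTheoretical = nrow(ladder))
  class(out) <- "akhAnnotation"
  out
}

#' @export
print.akhAnnotation <- function(x, ...) {
  cat("CID annotation: ", nrow(x$matches), " matched ions, coverage ",
      sprintf("%.2f", x$coverage), " (b ",
      sprintf("%.2f", x$coverageBySeries[["b"]]), ", y ",
      sprintf("%.2f", x$coverageBySeries[["y"]]), "), ",
      x$unmatchedPeaks, " unmatched peaks\n", sep = "")
  invisible(x)
}

#' Deterministic spectrum/peptide match score
#'
#' `score = (number of matched theoretical ions) + coverage`.  The integer
#' part rewards explained peaks; the fractional coverage term breaks ties
#' between candidates explaining equally many ions with different backbone
#' support.  Higher is better; the score is invariant under peak order.
#'
#' @inheritParams annotateSpectrum
#' @return A non-negative number.
#' @export
matchScore <- function(s, p, tol = 0.3, losses = c("none", "H2O", "NH3")) {
  a <- annotateSpectrum(s, p, tol = tol, losses = losses)
  nrow(a$matches) + a$coverage
}

#' Isobaric residue ambiguities of an assigned sequence
#'
#' Reports, for every Leu/Ile and Gln/Lys position, the alternative residue
#' that is indistinguishable (Leu/Ile, delta exactly 0) or nearly so
#' (Gln/Lys, delta +/- 0.0364 Da) at a stated precursor mass accuracy.  A
#' Gln/Lys swap is resolvable iff |delta| exceeds the absolute tolerance
#' implied by `tolPpm` at `precursorMz`; Leu/Ile is never mass-resolvable
#' (the wet-lab resolution is LC co-elution, represented here only by the
#' `resolvable = FALSE` flag).
#'
#' @param p An [AkhPeptide-class].
#' @param tolPpm Mass accuracy in ppm (> 0).
#' @param precursorMz Precursor m/z at which the accuracy applies; defaults
#'   to the peptide's own (M+H)+.
#' @return data.frame with columns `position`, `observed`, `alternative`,
#'   `deltaDa`, `resolvable`.
#' @examples
#' isobaricAlternatives(parseAkhNotation("pELTFSSGWGQa"), tolPpm = 5)
#' @export
isobaricAlternatives <- function(p, tolPpm, precursorMz = ionMz(p, "H")) {
  stopifnot(is(p, "AkhPeptide"))
  if (tolPpm <= 0) stop("tolPpm must be positive")
  res <- residues(p)
  swap <- c(L = "I", I = "L", Q = "K", K = "Q")
  hit <- which(res %in% names(swap))
  ## position 1 of a pyroglutamate peptide is the locked pE ring, not a free
  ## residue, but E is never in the swap set so no special case is needed
  if (!length(hit))
    return(data.frame(position = integer(0), observed = character(0),
                      alternative = character(0), deltaDa = numeric(0),
                      resolvable = logical(0)))
  observed <- res[hit]
  alternative <- unname(swap[observed])
  delta <- vapply(seq_along(hit), function(i)
    residueMass(alternative[i]) - residueMass(observed[i]), numeric(1))
  tolDa <- tolPpm * precursorMz * 1e-6
  data.frame(position = hit, observed = observed, alternative = alternative,
             deltaDa = delta, resolvable = abs(delta) > tolDa)
}
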