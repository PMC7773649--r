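## Mascot Generic Format (MGF) peak-list I/O.
##
## MGF is a line-oriented text format: each spectrum sits between BEGIN IONS
## and END IONS, with KEY=VALUE headers (PEPMASS, TITLE, ...) followed by one
## "m/z intensity" pair per line.

#' Write spectra to an MGF file
#'
#' @param spectra A [CidSpectrum-class] or list of them.
#' @param path Output file path.
#' @param titles Optional character vector of TITLE values.
#' @return `path`, invisibly.
#' @export
writeMgf <- function(spectra, path, titles = NULL) {
  if (is(spectra, "CidSpectrum")) spectra <- list(spectra)
  if (is.null(titles))
    titles <- sprintf("spectrum_%d", seq_along(spectra))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", titles[i]),
      sprintf("PEPMASS=%.6f", precursorMz(s)),
      "CHARGE=1+",
      sprintf("%.6f %.4f", s@mz, s@intensity),
      "END IONS", ""
    ), con)
  }
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' @param path Path to an MGF file.
#' @param resolutionClass Resolution class stamped on the returned spectra.
#' @return Named list of [CidSpectrum-class] objects (names from TITLE).
#' @export
readMgf <- function(path, resolutionClass = "ion_trap") {
  lines <- trimws(readLines(path))
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF file: unbalanced BEGIN IONS/END IONS in ", path)
  out <- vector("list", length(begins))
  nms <- character(length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    headers <- grep("=", block, fixed = TRUE, value = TRUE)
    peaks <- block[!grepl("=", block, fixed = TRUE) & nzchar(block)]
    kv <- strsplit(headers, "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, character(1), 1L))
    vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1))
    pepmass <- vals[match("PEPMASS", keys)]
    if (is.na(pepmass)) stop("spectrum ", i, " in ", path, " lacks PEPMASS")
    ## PEPMASS may carry a second (intensity) token
    pepmass <- as.numeric(strsplit(pepmass, "[[:space:]]+")[[1L]][1L])
    nms[i] <- if (!is.na(match("TITLE", keys))) vals[match("TITLE", keys)]
              else sprintf("spectrum_%d", i)
    if (length(peaks)) {
      mat <- do.call(rbind, lapply(strsplit(peaks, "[[:space:]]+"), function(x)
        as.numeric(x[1:2])))
      if (anyNA(mat)) stop("unparseable peak line in spectrum ", i, " of ", path)
      out[[i]] <- CidSpectrum(pepmass, mat[, 1L], mat[, 2L], resolutionClass)
    } else {
      out[[i]] <- CidSpectrum(pepmass, resolutionClass = resolutionClass)
    }
  }
  names(out) <- nms
  out
}

#' Write an annotation report as TSV
#'
#' One row per matched peak: peak m/z, intensity, ion label (e.g. `b3-H2O`),
#' theoretical m/z and signed error in Da.
#'
#' @param annotation Result of [annotateSpectrum()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeAnnotationTsv <- function(annotation, path) {
  stopifnot(inherits(annotation, "akhAnnotation"))
  m <- annotation$matches
  utils::write.table(
    data.frame(mz = sprintf("%.6f", m$peakMz),
               intensity = sprintf("%.4f", m$intensity),
               ion = m$label,
               theoretical_mz = sprintf("%.6f", m$theoreticalMz),
               error_da = sprintf("%+.6f", m$errorDa)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
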