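#' Parse the compact AKH sequence notation
#'
#' The notation used for mature and precursor-form AKHs writes the
#' pyroglutamate N-terminus as a leading `pE`, the amidated C-terminus as a
#' trailing lowercase `a`, and a free-acid C-terminus as a trailing `-OH`;
#' interior characters are uppercase one-letter residue codes.  Examples:
#' `pELTFTSSWGa` (Manse-AKH, nonapeptide amide), `pELTFTSSWGGK-OH`
#' (Vanca-AKH, free-acid undecapeptide).
#'
#' @param text A single notation string.
#' @return An [AkhPeptide-class].
#' @examples
#' parseAkhNotation("pELTFTSSWGa")
#' parseAkhNotation("pELTFTSSWGGK-OH")
#' @export
parseAkhNotation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("empty notation string")
  if (!startsWith(text, "pE"))
    stop("missing 'pE' prefix in notation '", text, "'")
  body <- substring(text, 3L)
  if (endsWith(body, "-OH")) {
    cTerm <- "free_acid"
    body <- substring(body, 1L, nchar(body) - 3L)
  } else if (endsWith(body, "a")) {
    cTerm <- "amide"
    body <- substring(body, 1L, nchar(body) - 1L)
  } else {
    stop("missing terminus marker in notation '", text,
         "' (expected trailing 'a' or '-OH')")
  }
  codes <- strsplit(body, "", fixed = TRUE)[[1L]]
  bad <- setdiff(codes, rownames(.RESIDUE_COMPOSITIONS))
  if (length(bad))
    stop("unknown residue code '", bad[1L], "' in notation '", text, "'")
  AkhPeptide(c("E", codes), nTerm = "pyroglutamate", cTerm = cTerm)
}

#' Format an AkhPeptide in the compact notation
#'
#' Inverse of [parseAkhNotation()]; the round trip is bit-exact.
#'
#' @param p An [AkhPeptide-class].
#' @return A single notation string.
#' @export
formatAkhNotation <- function(p) {
  stopifnot(is(p, "AkhPeptide"))
  res <- residues(p)
  head <- if (identical(nTerm(p), "pyroglutamate")) {
    paste0("pE", paste0(res[-1L], collapse = ""))
  } else {
    paste0(res, collapse = "")
  }
  tail <- if (identical(cTerm(p), "amide")) "a" else "-OH"
  paste0(head, tail)
}

#' Write peptides as FASTA with terminus tags
#'
#' Writes the bare residue string (one-letter codes, including the initial E
#' of pyroglutamate) with header key-value tags `nterm=pGlu|free` and
#' `cterm=amide|free` so the terminal chemistry survives the trip through a
#' sequence-only format.
#'
#' @param peptides List of [AkhPeptide-class] objects.
#' @param names Character vector of record names (defaults to the notation).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [readAkhFasta()]
#' @export
writeAkhFasta <- function(peptides, path, names = NULL) {
  if (is(peptides, "AkhPeptide")) peptides <- list(peptides)
  if (is.null(names))
    names <- vapply(peptides, formatAkhNotation, character(1))
  lines <- unlist(lapply(seq_along(peptides), function(i) {
    p <- peptides[[i]]
    nt <- if (identical(nTerm(p), "pyroglutamate")) "pGlu" else "free"
    ct <- if (identical(cTerm(p), "amide")) "amide" else "free"
    c(sprintf(">%s nterm=%s cterm=%s", names[i], nt, ct),
      paste0(residues(p), collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read peptides from tagged FASTA
#'
#' @param path FASTA file written by [writeAkhFasta()] (or following the same
#'   header tag convention).
#' @return Named list of [AkhPeptide-class] objects.
#' @export
readAkhFasta <- function(path) {
  lines <- readLines(path)
  headers <- grep("^>", lines)
  if (!length(headers)) stop("no FASTA records in ", path)
  ends <- c(headers[-1L] - 1L, length(lines))
  out <- vector("list", length(headers))
  nms <- character(length(headers))
  for (i in seq_along(headers)) {
    h <- sub("^>", "", lines[headers[i]])
    fields <- strsplit(h, "[[:space:]]+")[[1L]]
    nms[i] <- fields[1L]
    nt <- sub("^nterm=", "", grep("^nterm=", fields, value = TRUE)[1L])
    ct <- sub("^cterm=", "", grep("^cterm=", fields, value = TRUE)[1L])
    seqline <- paste0(lines[(headers[i] + 1L):ends[i]], collapse = "")
    out[[i]] <- AkhPeptide(
      seqline,
      nTerm = if (identical(nt, "pGlu")) "pyroglutamate" else "free",
      cTerm = if (identical(ct, "amide")) "amide" else "free_acid"
    )
  }
  names(out) <- nms
  out
}
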