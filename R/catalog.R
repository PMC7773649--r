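## The packaged lepidopteran AKH catalog.
##
## One row per species x peptide, transcribed from the published distribution
## table: higher taxonomy (clade, superfamily, family), species binomial,
## peptide code name, canonical sequence notation, the printed (M+H)+ value,
## the sequence exactly as printed (a few cells carry letter transpositions
## that are mass-identical anagrams of the canonical sequence), an evidence
## class, and the source reference.

.CATALOG_COLUMNS <- c("clade", "superfamily", "family", "species",
                      "peptide_name", "notation", "printed_mh",
                      "printed_sequence", "evidence", "reference")
.EVIDENCE_LEVELS <- c("ms_confirmed", "predicted_only",
                      "incompletely_processed")

#' Load the AKH catalog
#'
#' Reads and validates the packaged (or a user-supplied) tab-separated
#' catalog.  Every row must parse: the sequence notation must be valid, the
#' printed mass positive, the evidence class known, and the
#' `incompletely_processed` class must coincide exactly with a free-acid
#' C-terminus.
#'
#' @param path Path to a catalog TSV; defaults to the packaged table.
#' @return A data.frame of class `c("akhCatalog", "data.frame")` with the
#'   columns listed above.
#' @examples
#' cat76 <- loadCatalog()
#' length(unique(cat76$species))
#' @export
loadCatalog <- function(path = system.file("extdata", "akh_catalog.tsv",
                                           package = "akhpep")) {
  if (!nzchar(path) || !file.exists(path)) stop("catalog file not found")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  missing <- setdiff(.CATALOG_COLUMNS, names(df))
  if (length(missing))
    stop("catalog lacks column(s): ", paste(missing, collapse = ", "))
  df$printed_mh <- as.numeric(df$printed_mh)
  for (i in seq_len(nrow(df))) {
    row <- function(msg) stop("catalog row ", i, " (", df$species[i], " / ",
                              df$peptide_name[i], "): ", msg)
    parsed <- tryCatch(parseAkhNotation(df$notation[i]),
                       error = function(e) row(conditionMessage(e)))
    if (is.na(df$printed_mh[i]) || df$printed_mh[i] <= 0)
      row("printed (M+H)+ must be a positive number")
    if (!df$evidence[i] %in% .EVIDENCE_LEVELS)
      row(paste0("unknown evidence class '", df$evidence[i], "'"))
    freeAcid <- identical(cTerm(parsed), "free_acid")
    if (freeAcid != identical(df$evidence[i], "incompletely_processed"))
      row("evidence 'incompletely_processed' must coincide with a free-acid C-terminus")
  }
  class(df) <- c("akhCatalog", "data.frame")
  df
}

#' Validate catalog masses and printed-sequence anagrams
#'
#' Recomputes the theoretical (M+H)+ of every canonical sequence and compares
#' it with the printed value; additionally, wherever the printed sequence
#' differs from the canonical one (typesetting letter transpositions), checks
#' that the two are composition-identical anagrams.
#'
#' @param entries An `akhCatalog` data.frame.
#' @param tolDa Tolerance absorbing 4-decimal rounding of the printed values.
#' @return A list: `perEntry` (data.frame with computed m/z, deviation, and
#'   anagram status), `maxDeviation`, `failures` (rows exceeding `tolDa`),
#'   and `anagramFailures`.
#' @export
validateMasses <- function(entries, tolDa = 5e-4) {
  stopifnot(inherits(entries, "data.frame"))
  computed <- vapply(entries$notation,
                     function(nt) ionMz(parseAkhNotation(nt), "H"),
                     numeric(1), USE.NAMES = FALSE)
  deviation <- abs(computed - entries$printed_mh)
  sameComposition <- vapply(seq_len(nrow(entries)), function(i) {
    if (identical(entries$printed_sequence[i], entries$notation[i])) return(TRUE)
    a <- peptideComposition(parseAkhNotation(entries$notation[i]))
    b <- peptideComposition(parseAkhNotation(entries$printed_sequence[i]))
    identical(a, b)
  }, logical(1))
  perEntry <- data.frame(species = entries$species,
                         peptide_name = entries$peptide_name,
                         notation = entries$notation,
                         printed_mh = entries$printed_mh,
                         computed_mh = computed,
                         deviationDa = deviation,
                         printedSequenceIsAnagram = sameComposition)
  list(perEntry = perEntry,
       maxDeviation = max(deviation),
       failures = perEntry[deviation > tolDa, , drop = FALSE],
       anagramFailures = perEntry[!sameComposition, , drop = FALSE])
}

#' Summarize the catalog
#'
#' Counts are computed the way the survey reports them: species as distinct
#' binomials; the unique-AKH tally over distinct canonical sequences with
#' `ms_confirmed` evidence (the incompletely processed free-acid form is
#' excluded); length classes over those unique confirmed sequences;
#' per-species counts over all mature (non-free-acid) AKHs.
#'
#' @param entries An `akhCatalog` data.frame.
#' @return A list of class `"akhCatalogSummary"`.
#' @export
summarizeCatalog <- function(entries) {
  stopifnot(inherits(entries, "data.frame"))
  confirmed <- entries[entries$evidence == "ms_confirmed", , drop = FALSE]
  uniqueSeqs <- unique(confirmed$notation)
  lens <- vapply(uniqueSeqs, function(nt) length(parseAkhNotation(nt)),
                 integer(1), USE.NAMES = FALSE)
  lengthClassCounts <- c(`8` = sum(lens == 8L), `9` = sum(lens == 9L),
                         `10` = sum(lens == 10L))
  mature <- entries[entries$evidence != "incompletely_processed", , drop = FALSE]
  perSpecies <- if (nrow(mature))
    sort(table(mature$species), decreasing = TRUE) else table(character(0))
  perSuperfamily <- if (nrow(entries))
    lapply(split(entries$peptide_name, entries$superfamily), unique)
  else list()
  structure(list(
    speciesCount = length(unique(entries$species)),
    confirmedPeptideCount = length(uniqueSeqs),
    confirmedPeptides = sort(unique(confirmed$peptide_name)),
    lengthClassCounts = lengthClassCounts,
    perSuperfamily = perSuperfamily,
    perSpeciesCounts = perSpecies,
    maxAkhsPerSpecies = if (length(perSpecies)) max(perSpecies) else 0L
  ), class = "akhCatalogSummary")
}

#' @export
print.akhCatalogSummary <- function(x, ...) {
  cat("AKH catalog: ", x$speciesCount, " species; ",
      x$confirmedPeptideCount, " unique biochemically confirmed AKHs (",
      x$lengthClassCounts[["10"]], " deca / ",
      x$lengthClassCounts[["9"]], " nona / ",
      x$lengthClassCounts[["8"]], " octa); max ",
      x$maxAkhsPerSpecies, " AKHs in one species\n", sep = "")
  invisible(x)
}

#' Query the catalog
#'
#' Conjunctive filtering on taxonomy, peptide name, or peptide length; input
#' row order is preserved.
#'
#' @param entries An `akhCatalog` data.frame.
#' @param ... Named filters among `clade`, `superfamily`, `family`,
#'   `species`, `peptide_name`, `length` (peptide length in residues),
#'   `evidence`.  Each may be a vector (membership test).
#' @return The filtered data.frame.
#' @examples
#' cat76 <- loadCatalog()
#' queryCatalog(cat76, superfamily = "Noctuoidea", peptide_name = "Helze-HrTH")
#' @export
queryCatalog <- function(entries, ...) {
  stopifnot(inherits(entries, "data.frame"))
  filters <- list(...)
  allowed <- c("clade", "superfamily", "family", "species", "peptide_name",
               "length", "evidence")
  bad <- setdiff(names(filters), allowed)
  if (length(bad) || any(!nzchar(names(filters))))
    stop("unknown filter key(s): ", paste(bad, collapse = ", "))
  keep <- rep(TRUE, nrow(entries))
  for (key in names(filters)) {
    keep <- keep & if (key == "length") {
      lens <- vapply(entries$notation,
                     function(nt) length(parseAkhNotation(nt)), integer(1),
                     USE.NAMES = FALSE)
      lens %in% filters[[key]]
    } else {
      entries[[key]] %in% filters[[key]]
    }
  }
  entries[keep, , drop = FALSE]
}

#' Export the catalog
#'
#' TSV export round-trips bit-exactly through [loadCatalog()]; FASTA export
#' writes one record per row with species, peptide name and terminus tags in
#' the header.
#'
#' @param entries An `akhCatalog` data.frame.
#' @param path Output path.
#' @param format `"tsv"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
exportCatalog <- function(entries, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  stopifnot(inherits(entries, "data.frame"))
  if (format == "tsv") {
    out <- entries[, .CATALOG_COLUMNS]
    out$printed_mh <- sprintf("%.4f", out$printed_mh)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    peptides <- lapply(entries$notation, parseAkhNotation)
    names <- sprintf("%s|%s", gsub(" ", "_", entries$species),
                     gsub(" ", "_", entries$peptide_name))
    writeAkhFasta(peptides, path, names = names)
  }
  invisible(path)
}
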