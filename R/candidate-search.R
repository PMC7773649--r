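## Grammar-constrained candidate identification.
##
## The AKH family is tightly constrained: pyroglutamate start, amidated end,
## 8-10 residues, position 2 aliphatic/aromatic (Leu in all Lepidoptera),
## position 3 Thr/Asn, position 4 Phe/Tyr, position 5 Thr/Ser, Trp8, Gly9
## (nona/decapeptides), with positions 6, 7 and 10 free.  This makes
## exhaustive enumeration against a precursor mass tractable and turns the
## manual sequence assignment of ion-trap CID spectra into a reproducible
## search.

.FREE_POSITIONS <- c(6L, 7L, 10L)

#' AKH family grammar
#'
#' @param variant `"general"` (position 2 in L/I/V/F/Y) or `"lepidopteran"`
#'   (position 2 restricted to Leu: no Val or Ile occurs at position 2 in any
#'   lepidopteran AKH).
#' @return A list of class `"akhGrammar"` with per-position allowed residue
#'   sets for lengths 8-10 and the terminal requirements.
#' @export
akhGrammar <- function(variant = c("general", "lepidopteran")) {
  variant <- match.arg(variant)
  all20 <- rownames(.RESIDUE_COMPOSITIONS)
  pos2 <- if (variant == "lepidopteran") "L" else c("L", "I", "V", "F", "Y")
  structure(list(
    variant = variant,
    positions = list(
      `1` = "E",          # the pE ring; notation letter is E
      `2` = pos2,
      `3` = c("T", "N"),
      `4` = c("F", "Y"),
      `5` = c("T", "S"),
      `6` = all20,
      `7` = all20,
      `8` = "W",
      `9` = "G",          # applies when length >= 9
      `10` = all20
    ),
    lengths = 8:10,
    nTerm = "pyroglutamate",
    cTerm = "amide"
  ), class = "akhGrammar")
}

#' Check a peptide against the AKH grammar
#'
#' @param p An [AkhPeptide-class].
#' @param grammar An [akhGrammar()] object.
#' @return A list with `pass` (logical) and `violations` (data.frame with
#'   columns `type`, `position`, `found`, `allowed`); terminal- and
#'   length-state violations are typed separately from positional ones.
#' @examples
#' grammarCheck(parseAkhNotation("pELTFTSSWGa"), akhGrammar("lepidopteran"))
#' @export
grammarCheck <- function(p, grammar = akhGrammar()) {
  stopifnot(is(p, "AkhPeptide"), inherits(grammar, "akhGrammar"))
  v <- list()
  add <- function(type, position, found, allowed)
    v[[length(v) + 1L]] <<- data.frame(
      type = type, position = position, found = found,
      allowed = paste0(allowed, collapse = "/"))
  n <- length(p)
  if (!n %in% grammar$lengths)
    add("length", NA_integer_, as.character(n),
        as.character(grammar$lengths))
  if (!identical(nTerm(p), grammar$nTerm))
    add("n_terminus", NA_integer_, nTerm(p), grammar$nTerm)
  if (!identical(cTerm(p), grammar$cTerm))
    add("c_terminus", NA_integer_, cTerm(p), grammar$cTerm)
  res <- residues(p)
  for (i in seq_len(min(n, 10L))) {
    allowed <- grammar$positions[[as.character(i)]]
    if (i == 9L && n < 9L) next
    if (i > n) next
    if (!res[i] %in% allowed)
      add("position", i, res[i], allowed)
  }
  viol <- if (length(v)) do.call(rbind, v) else
    data.frame(type = character(0), position = integer(0),
               found = character(0), allowed = character(0))
  list(pass = nrow(viol) == 0L, violations = viol)
}

## Internal: enumeration alphabets with Leu/Ile collapsed to "L" (their
## residue masses are identical, so enumeration over both would only double
## the space without adding mass information).
.collapseLeuIle <- function(x) sort(unique(sub("^I$", "L", x)))

## Internal: cached full enumeration tables per grammar variant — for each
## length, the neutral monoisotopic mass and notation of every sequence in
## the grammar's cartesian product (Leu/Ile collapsed).  ~60k sequences for
## the lepidopteran variant; built once per session.
.enumCache <- new.env(parent = emptyenv())

.enumerationTables <- function(grammar) {
  key <- grammar$variant
  if (!is.null(.enumCache[[key]])) return(.enumCache[[key]])
  sets <- lapply(grammar$positions, .collapseLeuIle)
  tables <- lapply(grammar$lengths, function(len) {
    alphabets <- sets[as.character(seq_len(len))]
    varPos <- which(vapply(alphabets, length, integer(1)) > 1L)
    constMass <- sum(.RESIDUE_MASSES[
      c("pE", unlist(alphabets[setdiff(seq_len(len), c(1L, varPos))]))]) +
      .MASS_NH3
    grid <- do.call(expand.grid,
                    c(alphabets[varPos], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE))
    mz <- constMass + Reduce(`+`, lapply(grid, function(col)
      unname(.RESIDUE_MASSES[col])))
    ## assemble notations vectorized: fixed template with variable slots
    template <- vapply(alphabets, `[`, character(1), 1L)
    cols <- replicate(len, NULL, simplify = FALSE)
    for (i in seq_len(len))
      cols[[i]] <- if (i %in% varPos) grid[[match(i, varPos)]]
                   else rep(template[i], nrow(grid))
    body <- do.call(paste0, cols[-1L])
    list(notation = paste0("pE", body, "a"), mz = mz)
  })
  names(tables) <- as.character(grammar$lengths)
  .enumCache[[key]] <- tables
  tables
}

#' Enumerate grammar-conforming candidates for a precursor mass
#'
#' Exhaustively enumerates the grammar's cartesian product over lengths 8-10
#' and keeps sequences whose theoretical adduct m/z falls within `tol` of the
#' observed precursor.  Leu and Ile are collapsed to a single symbol (written
#' `L`) during enumeration; every reported candidate containing L/I positions
#' stands for the whole set of its mass-identical Leu/Ile variants
#' (`nLeuIleSites` counts them).
#'
#' @param precursorMz Observed precursor m/z (Da, charge 1).
#' @param adduct Adduct name, default `"H"`.
#' @param grammar An [akhGrammar()] object.
#' @param tol Mass window half-width in Da (> 0).
#' @param cap Maximum candidate count; exceeding it raises an explicit
#'   overflow error rather than silently truncating.
#' @return A list of class `"akhCandidateSet"`: `candidates` (data.frame with
#'   `notation`, `mz`, `errorDa`, `nLeuIleSites`, ordered by ascending
#'   absolute error then lexicographically), `precursorMz`, `adduct`, `tol`,
#'   `searchSpace` (sequences enumerated per length).
#' @examples
#' cs <- enumerateCandidates(988.4887, grammar = akhGrammar("lepidopteran"),
#'                           tol = 0.005)
#' head(cs$candidates)
#' @export
enumerateCandidates <- function(precursorMz, adduct = "H",
                                grammar = akhGrammar(), tol = 0.005,
                                cap = 100000L) {
  if (tol <= 0) stop("tolerance must be positive")
  shift <- .ADDUCT_SHIFTS[[adduct]]
  if (is.null(shift)) stop("unknown adduct: '", adduct, "'")

  tables <- .enumerationTables(grammar)
  searchSpace <- vapply(tables, function(t) length(t$mz), integer(1))
  found <- lapply(tables, function(t) {
    ## neutral-mass table; apply the adduct shift at query time
    hit <- which(abs(t$mz + shift - precursorMz) <= tol)
    data.frame(notation = t$notation[hit], mz = t$mz[hit] + shift,
               errorDa = t$mz[hit] + shift - precursorMz)
  })
  cand <- do.call(rbind, found)
  if (nrow(cand) > cap)
    stop("candidate set overflow: ", nrow(cand), " sequences exceed cap ",
         cap, "; tighten the tolerance")
  cand <- cand[order(abs(cand$errorDa), cand$notation), , drop = FALSE]
  cand$nLeuIleSites <- vapply(strsplit(sub("a$", "", sub("^pE", "", cand$notation)),
                                       "", fixed = TRUE),
                              function(x) sum(x == "L"), integer(1))
  rownames(cand) <- NULL
  structure(list(candidates = cand, precursorMz = precursorMz,
                 adduct = adduct, tol = tol, searchSpace = searchSpace,
                 grammar = grammar$variant),
            class = "akhCandidateSet")
}

#' @export
print.akhCandidateSet <- function(x, ...) {
  cat("AKH candidate set: ", nrow(x$candidates), " candidates within ",
      x$tol, " Da of m/z ", sprintf("%.4f", x$precursorMz), " (+", x$adduct,
      "), search space ", sum(x$searchSpace), " sequences (",
      x$grammar, " grammar)\n", sep = "")
  invisible(x)
}

#' Rank candidates against a CID spectrum
#'
#' Orders the candidate set by [matchScore()] (descending), breaking ties by
#' absolute precursor error and then lexicographically.  With an empty
#' spectrum all scores are zero and the order falls back to precursor-error
#' order.  Candidates whose fragment ladders are identical to the leader
#' (mass-identical Leu/Ile variants are already collapsed; this catches any
#' remaining exact ladder ties) are flagged as a tied leading group.
#'
#' @param cs An `"akhCandidateSet"` from [enumerateCandidates()].
#' @param s A [CidSpectrum-class].
#' @param tol Fragment-match tolerance passed to [matchScore()].
#' @return The candidate set with `candidates` gaining a `score` column,
#'   re-ordered, plus a `tiedLeaders` integer count.
#' @export
rankCandidates <- function(cs, s, tol = 0.3) {
  stopifnot(inherits(cs, "akhCandidateSet"), is(s, "CidSpectrum"))
  cand <- cs$candidates
  if (!nrow(cand)) stop("empty candidate set")
  cand$score <- vapply(cand$notation, function(nt)
    matchScore(s, parseAkhNotation(nt), tol = tol), numeric(1),
    USE.NAMES = FALSE)
  ord <- order(-cand$score, abs(cand$errorDa), cand$notation)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  tied <- if (nrow(cand)) sum(cand$score == cand$score[1L] &
                              abs(cand$mz - cand$mz[1L]) < 1e-9) else 0L
  cs$candidates <- cand
  cs$tiedLeaders <- as.integer(tied)
  cs
}

#' Map a precursor-processing intermediate to its mature AKH
#'
#' AKH precursors donate the C-terminal amide from a glycine followed by
#' basic residue(s): a free-acid peptide ending in Gly-(Lys/Arg)* is an
#' incompletely processed form whose mature hormone is obtained by stripping
#' the basic residues and converting the now-terminal Gly into the amide of
#' the remaining chain.  Vanca-AKH (pELTFTSSWGGK-OH) maps to Manse-AKH this
#' way.
#'
#' @param p An [AkhPeptide-class].
#' @param catalog Optional catalog data.frame (from [loadCatalog()]) used to
#'   name the mature peptide.
#' @return `NULL` when the rule does not apply (already amidated, or the
#'   free-acid tail is not Gly-(K/R)*); otherwise a list with `mature`
#'   (AkhPeptide), `matureNotation`, and `catalogName` (peptide name or NA).
#' @export
detectProcessingIntermediate <- function(p, catalog = NULL) {
  stopifnot(is(p, "AkhPeptide"))
  if (!identical(cTerm(p), "free_acid")) return(NULL)
  res <- residues(p)
  i <- length(res)
  while (i > 1L && res[i] %in% c("K", "R")) i <- i - 1L
  if (i < 2L || res[i] != "G") return(NULL)
  matureRes <- res[seq_len(i - 1L)]   # drop the amide-donating Gly too
  mature <- AkhPeptide(matureRes, nTerm = nTerm(p), cTerm = "amide")
  notation <- formatAkhNotation(mature)
  name <- NA_character_
  if (!is.null(catalog)) {
    hit <- match(notation, catalog$notation)
    if (!is.na(hit)) name <- catalog$peptide_name[hit]
  }
  list(mature = mature, matureNotation = notation, catalogName = name)
}
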