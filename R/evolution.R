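## Codon-level minimal-mutation arithmetic and the AKH mutation network.
##
## The currency of the analysis is the minimal number of nucleotide point
## mutations needed to interconvert two residues under the standard nuclear
## genetic code, minimized over all synonymous codon pairs (no codon-usage
## weighting).  Chain elongation (the family's C-terminal octa -> nona ->
## decapeptide growth) is typed as its own event costing 1 per added
## residue.

## Standard nuclear genetic code, DNA alphabet.  Built once from base
## machinery: 64 codons in fixed TCAG order.
.GENETIC_CODE <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT, TTC, TTA, TTG, TCT, ... TGG
    "LLLLPPPPHHQQRRRR",   # CTT ... CGG
    "IIIMTTTTNNKKSSRR",   # ATT ... AGG
    "VVVVAAAADDEEGGGG"),  # GTT ... GGG
    "", fixed = TRUE)[[1L]]
  codons <- character(64); k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  names(aa) <- codons
  aa
})

#' The standard genetic code
#'
#' @return Named character vector: 64 DNA codons mapping to one-letter amino
#'   acids, with `"*"` for the three stop codons.
#' @export
geneticCode <- function() .GENETIC_CODE

## Lazy cache of the 20x20 minimal distance matrix.
.minCodonCache <- new.env(parent = emptyenv())

#' Minimal codon substitution distance between two residues
#'
#' Minimum Hamming distance over all (codon, codon) pairs encoding the two
#' residues under the standard code.  Symmetric; 0 iff the residues are
#' identical; at most 3.  Asn -> Gly requires 2 nucleotide changes, the one
#' step in the AKH family network that is not a single point mutation.
#'
#' @param aaFrom,aaTo One-letter residue codes.
#' @return Integer distance in nucleotides.
#' @examples
#' minCodonDistance("N", "G")  # 2
#' minCodonDistance("S", "T")  # 1
#' @export
minCodonDistance <- function(aaFrom, aaTo) {
  m <- minCodonDistanceMatrix()
  if (!aaFrom %in% rownames(m)) stop("unknown residue code: '", aaFrom, "'")
  if (!aaTo %in% rownames(m)) stop("unknown residue code: '", aaTo, "'")
  m[aaFrom, aaTo]
}

#' Full 20x20 minimal codon distance matrix
#'
#' @return Integer matrix over the 20 standard residues.
#' @export
minCodonDistanceMatrix <- function() {
  if (!is.null(.minCodonCache$m)) return(.minCodonCache$m)
  code <- .GENETIC_CODE
  sense <- code[code != "*"]
  codonMat <- do.call(rbind, strsplit(names(sense), "", fixed = TRUE))
  aas <- sort(unique(sense))
  ## pairwise codon Hamming distances (61 x 61), then min over groups
  hamming <- matrix(0L, nrow(codonMat), nrow(codonMat))
  for (p in 1:3)
    hamming <- hamming + outer(codonMat[, p], codonMat[, p], `!=`)
  m <- matrix(NA_integer_, length(aas), length(aas),
              dimnames = list(aas, aas))
  for (a in aas) for (b in aas)
    m[a, b] <- min(hamming[sense == a, sense == b])
  .minCodonCache$m <- m
  m
}

#' Per-position mutation profile between two AKH peptides
#'
#' Alignment is N-terminally anchored with C-terminal overhang only (the
#' pyroglutamate start is invariant and all length variation in the family
#' is C-terminal): shared positions are compared by minimal codon distance
#' and each extra C-terminal residue of the longer peptide counts as one
#' elongation event.  Total cost = substitution nucleotides + elongations;
#' symmetric in its arguments.
#'
#' @param a,b [AkhPeptide-class] objects (or notation strings).
#' @param alignment Only `"nterm_anchored"` is modeled; requesting anything
#'   else (e.g. gapped) is an error.
#' @return A list of class `"akhMutationEdge"`: `from`, `to` (notations),
#'   `perPosition` (integer vector over shared positions), `changes`
#'   (data.frame position/from/to/nt), `elongations`, `cost`.
#' @examples
#' peptideEditProfile("pELTFTSSWGa", "pELTFTSSWGGa")  # one elongation
#' @export
peptideEditProfile <- function(a, b, alignment = "nterm_anchored") {
  if (!identical(alignment, "nterm_anchored"))
    stop("only N-terminally anchored alignment is modeled; ",
         "gapped alignment is not supported")
  if (is.character(a)) a <- parseAkhNotation(a)
  if (is.character(b)) b <- parseAkhNotation(b)
  stopifnot(is(a, "AkhPeptide"), is(b, "AkhPeptide"))
  ra <- residues(a); rb <- residues(b)
  shared <- seq_len(min(length(ra), length(rb)))
  m <- minCodonDistanceMatrix()
  perPosition <- vapply(shared, function(i) m[ra[i], rb[i]], integer(1))
  diffs <- shared[perPosition > 0L]
  changes <- data.frame(position = diffs, from = ra[diffs], to = rb[diffs],
                        nt = perPosition[diffs])
  elong <- abs(length(ra) - length(rb))
  structure(list(from = formatAkhNotation(a), to = formatAkhNotation(b),
                 perPosition = perPosition, changes = changes,
                 elongations = elong,
                 cost = sum(perPosition) + elong),
            class = "akhMutationEdge")
}

#' @export
print.akhMutationEdge <- function(x, ...) {
  lab <- if (nrow(x$changes))
    paste(sprintf("%s%d>%s%d:%dnt", x$changes$from, x$changes$position,
                  x$changes$to, x$changes$position, x$changes$nt),
          collapse = ", ")
  else "no substitutions"
  cat(x$from, " <-> ", x$to, ": cost ", x$cost, " (", lab,
      if (x$elongations) paste0(" + ", x$elongations, " elongation(s)") else "",
      ")\n", sep = "")
  invisible(x)
}

## Internal: edge label like "S6>P6:1nt+1el"
.edgeLabel <- function(e) {
  subs <- if (nrow(e$changes))
    paste(sprintf("%s%d>%s%d:%dnt", e$changes$from, e$changes$position,
                  e$changes$to, e$changes$position, e$changes$nt),
          collapse = ",")
  else ""
  if (e$elongations > 0L)
    subs <- paste0(subs, if (nzchar(subs)) "+" else "",
                   e$elongations, "el")
  subs
}

#' Build the minimal-mutation network over a set of AKH peptides
#'
#' Connects every peptide pair whose total mutation cost (substitution
#' nucleotides plus elongation events) is at most `maxEdgeCost`.  If the
#' resulting graph is disconnected and `allowHypothetical`, a bounded,
#' deterministic search proposes grammar-conforming intermediate sequences
#' from the single-substitution (cost-1) neighborhood of the observed
#' peptides, adding those that bridge two or more components, up to `budget`
#' intermediates.  If the budget runs out before the graph is connected, the
#' partial graph is returned together with its component report (never an
#' exception).
#'
#' @param peptides Named character vector of notations (names become node
#'   labels) or a list of [AkhPeptide-class] objects.
#' @param maxEdgeCost Maximum edge cost (default 2: the family's largest
#'   single step, the two-nucleotide Asn/Gly exchange).
#' @param allowHypothetical Propose connecting intermediates?
#' @param budget Maximum number of hypothetical intermediates.
#' @param grammar Grammar hypothetical intermediates must satisfy.
#' @return A list of class `"akhMutationGraph"`: `graph` (igraph object with
#'   vertex attributes `name`, `label`, `status` and edge attributes `cost`,
#'   `substitutions`, `elongations`, `changes`, `flagged` — TRUE where any
#'   single position needs 2+ nucleotides), `connected`, `components`
#'   (membership per node), `hypotheticals` (notations added).
#' @export
buildMutationGraph <- function(peptides, maxEdgeCost = 2L,
                               allowHypothetical = FALSE, budget = 0L,
                               grammar = akhGrammar("lepidopteran")) {
  if (budget < 0L) stop("budget must be >= 0")
  if (is.list(peptides) && all(vapply(peptides, is, logical(1), "AkhPeptide")))
    peptides <- vapply(peptides, formatAkhNotation, character(1))
  notations <- unname(peptides)
  labels <- if (!is.null(names(peptides)) && all(nzchar(names(peptides))))
    names(peptides) else notations
  dup <- !duplicated(notations)
  notations <- notations[dup]; labels <- labels[dup]
  status <- rep("observed", length(notations))

  build <- function(notations, labels, status) {
    n <- length(notations)
    edges <- list()
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        e <- peptideEditProfile(notations[i], notations[j])
        if (e$cost <= maxEdgeCost)
          edges[[length(edges) + 1L]] <- data.frame(
            from = notations[i], to = notations[j], cost = e$cost,
            substitutions = sum(e$perPosition),
            elongations = e$elongations,
            changes = .edgeLabel(e),
            flagged = any(e$perPosition >= 2L))
      }
    }
    edf <- if (length(edges)) do.call(rbind, edges) else
      data.frame(from = character(0), to = character(0), cost = integer(0),
                 substitutions = integer(0), elongations = integer(0),
                 changes = character(0), flagged = logical(0))
    g <- igraph::graph_from_data_frame(
      edf, directed = FALSE,
      vertices = data.frame(name = notations, label = labels,
                            status = status))
    g
  }

  g <- build(notations, labels, status)
  hypo <- character(0)
  if (allowHypothetical && budget > 0L) {
    repeat {
      comp <- igraph::components(g)
      if (comp$no <= 1L || length(hypo) >= budget) break
      candidates <- .hypotheticalCandidates(notations, grammar)
      candidates <- setdiff(candidates, c(notations, hypo))
      added <- FALSE
      for (cand in candidates) {
        ## which components would this intermediate attach to?
        touched <- unique(vapply(seq_along(notations), function(i) {
          e <- peptideEditProfile(cand, notations[i])
          if (e$cost <= maxEdgeCost) comp$membership[[notations[i]]] else NA_integer_
        }, integer(1)))
        touched <- touched[!is.na(touched)]
        if (length(touched) >= 2L) {
          hypo <- c(hypo, cand)
          notations <- c(notations, cand)
          labels <- c(labels, cand)
          status <- c(status, "hypothetical")
          g <- build(notations, labels, status)
          added <- TRUE
          break
        }
      }
      if (!added) break
    }
  }
  comp <- igraph::components(g)
  structure(list(graph = g, connected = comp$no <= 1L,
                 components = comp$membership,
                 hypotheticals = hypo),
            class = "akhMutationGraph")
}

## Internal: deterministic (lexicographic) cost-1 substitution neighborhood
## of the observed peptides, restricted to grammar-conforming sequences.
.hypotheticalCandidates <- function(notations, grammar) {
  m <- minCodonDistanceMatrix()
  out <- character(0)
  for (nt in notations) {
    p <- parseAkhNotation(nt)
    res <- residues(p)
    for (pos in 2L:length(res)) {
      allowed <- grammar$positions[[as.character(pos)]]
      for (alt in allowed) {
        if (alt == res[pos] || m[res[pos], alt] != 1L) next
        res2 <- res; res2[pos] <- alt
        q <- AkhPeptide(res2, nTerm = nTerm(p), cTerm = cTerm(p))
        if (grammarCheck(q, grammar)$pass)
          out <- c(out, formatAkhNotation(q))
      }
    }
  }
  sort(unique(out))
}

#' @export
print.akhMutationGraph <- function(x, ...) {
  nv <- igraph::vcount(x$graph); ne <- igraph::ecount(x$graph)
  cat("AKH mutation graph: ", nv, " nodes (",
      sum(igraph::V(x$graph)$status == "hypothetical"), " hypothetical), ",
      ne, " edges; ", if (x$connected) "connected" else
        paste0(max(x$components), " components"), "\n", sep = "")
  invisible(x)
}

#' Export a mutation graph as DOT or JSON
#'
#' DOT export goes through igraph's writer; JSON writes nodes (with
#' observed/hypothetical status) and edges (with cost and per-position
#' change labels such as `"S6>P6:1nt"`).
#'
#' @param mg An `"akhMutationGraph"`.
#' @param path Output path.
#' @param format `"dot"` or `"json"`.
#' @return `path`, invisibly.
#' @export
exportMutationGraph <- function(mg, path, format = c("dot", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(mg, "akhMutationGraph"))
  if (format == "dot") {
    g2 <- mg$graph
    if (igraph::ecount(g2) > 0)   # DOT has no boolean type
      igraph::E(g2)$flagged <- as.integer(igraph::E(g2)$flagged)
    igraph::write_graph(g2, path, format = "dot")
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON export")
    v <- data.frame(notation = igraph::V(mg$graph)$name,
                    label = igraph::V(mg$graph)$label,
                    status = igraph::V(mg$graph)$status)
    e <- igraph::as_data_frame(mg$graph, what = "edges")
    jsonlite::write_json(list(nodes = v, edges = e), path,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
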