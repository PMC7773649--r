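## Paired pre/post metabolite-mobilization bioassay analysis.
##
## The assay design: a hemolymph sample is taken from a resting animal (0
## min), the animal is injected with water, a gland extract or a synthetic
## peptide, and a second sample is taken from the same individual 90 min
## later.  Lipids (vanillin-positive material) or carbohydrates
## (anthrone-positive material) are quantified in both samples, and the
## treatment effect is tested with Student's paired t-test at alpha = 0.05.

#' Assemble bioassay records
#'
#' @param animalId Identifier per animal (unique within a treatment group).
#' @param pre,post Metabolite concentrations (mg/ml) at 0 and 90 min; must
#'   be non-negative.
#' @param species,treatment,metabolite Metadata columns; `metabolite` is
#'   `"lipids"` or `"carbohydrates"`.
#' @return A data.frame of class `c("akhAssayRecords", "data.frame")`.
#' @export
assayRecords <- function(animalId, pre, post, species = "unspecified",
                         treatment = "unspecified", metabolite = "lipids") {
  if (any(pre < 0) || any(post < 0))
    stop("concentrations must be non-negative")
  if (!all(metabolite %in% c("lipids", "carbohydrates")))
    stop("metabolite must be 'lipids' or 'carbohydrates'")
  df <- data.frame(animal_id = animalId, species = species,
                   treatment = treatment, metabolite = metabolite,
                   pre_mg_per_ml = pre, post_mg_per_ml = post)
  class(df) <- c("akhAssayRecords", "data.frame")
  df
}

#' Read bioassay records from CSV
#'
#' Expects columns `animal_id`, `species`, `treatment`, `metabolite`,
#' `pre_mg_per_ml`, `post_mg_per_ml`.
#'
#' @param path CSV path.
#' @return An `akhAssayRecords` data.frame.
#' @export
readAssayCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "species", "treatment", "metabolite",
            "pre_mg_per_ml", "post_mg_per_ml")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("assay CSV lacks column(s): ", paste(missing, collapse = ", "))
  assayRecords(df$animal_id, df$pre_mg_per_ml, df$post_mg_per_ml,
               df$species, df$treatment, df$metabolite)
}

#' Paired pre/post analysis of one treatment x metabolite group
#'
#' Computes per-animal differences (90 min minus 0 min), their mean and
#' sample SD, and the two-sided paired t-test (`t = mean(d) / (sd(d) /
#' sqrt(n))`, n - 1 degrees of freedom).  Sidedness is two-sided: the assay
#' reports slightly negative, non-significant differences for water
#' controls, which a one-sided test could not produce.  A degenerate group
#' whose differences are exactly constant (sd = 0) with a non-zero mean is
#' reported with `t = Inf` (sign of the mean) and p at the smallest positive
#' double.
#'
#' @param records An `akhAssayRecords` data.frame (one treatment x
#'   metabolite group; an error is raised if several are mixed).
#' @param alpha Significance level for the flag (default 0.05).
#' @return A list of class `"akhAssayResult"`: `n`, `preMean`, `preSd`,
#'   `postMean`, `postSd`, `diffMean`, `diffSd`, `t`, `df`, `p`,
#'   `significant`.
#' @export
pairedAnalysis <- function(records, alpha = 0.05) {
  stopifnot(inherits(records, "data.frame"))
  if (nrow(records) < 2L)
    stop("paired analysis requires at least 2 animals")
  if (length(unique(records$treatment)) > 1L ||
      length(unique(records$metabolite)) > 1L)
    stop("records mix several treatment x metabolite groups; ",
         "split before analysis")
  if (anyDuplicated(records$animal_id))
    stop("duplicated animal_id: pre/post must be one row per animal")
  d <- records$post_mg_per_ml - records$pre_mg_per_ml
  n <- length(d)
  if (stats::sd(d) == 0) {
    tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else .Machine$double.xmin
  } else {
    tt <- stats::t.test(records$post_mg_per_ml, records$pre_mg_per_ml,
                        paired = TRUE, alternative = "two.sided")
    tstat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(
    n = n,
    preMean = mean(records$pre_mg_per_ml), preSd = stats::sd(records$pre_mg_per_ml),
    postMean = mean(records$post_mg_per_ml), postSd = stats::sd(records$post_mg_per_ml),
    diffMean = mean(d), diffSd = stats::sd(d),
    t = tstat, df = n - 1L, p = p,
    significant = p < alpha
  ), class = "akhAssayResult")
}

#' @export
print.akhAssayResult <- function(x, ...) {
  cat(sprintf(
    "Paired assay (n = %d): 0 min %.2f +/- %.2f, 90 min %.2f +/- %.2f\n",
    x$n, x$preMean, x$preSd, x$postMean, x$postSd))
  cat(sprintf("  difference %.2f +/- %.2f; t(%d) = %.2f, p = %.2g %s\n",
              x$diffMean, x$diffSd, x$df, x$t, x$p,
              if (x$significant) "(significant)" else "(NS)"))
  invisible(x)
}

#' Analyze all treatment x metabolite groups in a record set
#'
#' @param records An `akhAssayRecords` data.frame.
#' @param alpha Significance level.
#' @return A data.frame mirroring the published assay-table layout: one row
#'   per treatment x metabolite with n, means +/- SD, difference and p.
#' @export
assayTable <- function(records, alpha = 0.05) {
  groups <- split(records,
                  list(records$treatment, records$metabolite), drop = TRUE)
  rows <- lapply(groups, function(g) {
    r <- pairedAnalysis(g, alpha = alpha)
    data.frame(treatment = g$treatment[1L], metabolite = g$metabolite[1L],
               n = r$n, pre_mean = r$preMean, pre_sd = r$preSd,
               post_mean = r$postMean, post_sd = r$postSd,
               diff_mean = r$diffMean, diff_sd = r$diffSd,
               t = r$t, p = r$p,
               significance = if (r$significant) format(signif(r$p, 2)) else "NS")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate paired bioassay records
#'
#' Generates the paired design synthetically: baseline (0 min)
#' concentrations are Gaussian truncated at zero (concentrations cannot be
#' negative), and the 90 min value is the same animal's baseline plus a
#' fixed additive treatment effect plus Gaussian within-animal noise — so
#' pre and post are correlated within animals, the feature the paired test
#' exploits.  Reproducible given `seed`.
#'
#' @param n Number of animals (>= 1).
#' @param baselineMean,baselineSd Baseline concentration moments (mg/ml).
#' @param effect Additive treatment effect at 90 min (mg/ml; 0 = null).
#' @param noiseSd SD of the within-animal post-injection noise.
#' @param seed Integer seed.
#' @param ... Metadata passed to [assayRecords()].
#' @return An `akhAssayRecords` data.frame with `n` rows.
#' @examples
#' rec <- simulateAssay(7, baselineMean = 22.2, baselineSd = 6.2,
#'                      effect = 4.7, noiseSd = 2.5, seed = 42)
#' pairedAnalysis(rec)
#' @export
simulateAssay <- function(n, baselineMean, baselineSd, effect = 0,
                          noiseSd = 1, seed = 1L, ...) {
  if (n < 1L) stop("n must be >= 1")
  if (baselineSd < 0 || noiseSd < 0) stop("SDs must be non-negative")
  restore <- .withSeed(seed)
  on.exit(restore())
  pre <- pmax(stats::rnorm(n, baselineMean, baselineSd), 0)
  post <- pmax(pre + effect + stats::rnorm(n, 0, noiseSd), 0)
  assayRecords(animalId = seq_len(n), pre = pre, post = post, ...)
}
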