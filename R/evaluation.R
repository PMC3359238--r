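#' One-tailed Fisher's exact enrichment test
#'
#' Tests whether positives are enriched in the mixed set relative to the
#' control set: one-tailed (greater) hypergeometric p-value for the 2x2
#' table `[[r_m, N_m - r_m], [r_c, N_c - r_c]]`.
#'
#' @param r_m Positive count in the mixed set.
#' @param N_m Mixed set size.
#' @param r_c Positive count in the control set.
#' @param N_c Control set size.
#' @return The p-value.
#' @export
fisher_enrichment <- function(r_m, N_m, r_c, N_c) {
  stopifnot(r_m >= 0, r_c >= 0, r_m <= N_m, r_c <= N_c)
  tab <- matrix(c(r_m, N_m - r_m, r_c, N_c - r_c), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Enrichment of a prediction set, with significance
#'
#' Combines the set enrichment `E-value_h` with the one-tailed Fisher
#' p-value for a set of positives drawn from the mixed and control sets.
#'
#' @inheritParams fisher_enrichment
#' @param lengths A [corpus_lengths()] object of the two sets.
#' @return An `enrichment_result`: list with `r_m`, `r_c`, `N_m`, `N_c`,
#'   `e_value_h`, `p_value`.
#' @export
enrichment_result <- function(r_m, N_m, r_c, N_c, lengths) {
  structure(list(r_m = r_m, r_c = r_c, N_m = N_m, N_c = N_c,
                 e_value_h = compute_set_evalue(r_m, r_c, lengths),
                 p_value = fisher_enrichment(r_m, N_m, r_c, N_c)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("positives %d/%d mixed vs %d/%d control: E-value_h = %.2f, p = %.3g\n",
              x$r_m, x$N_m, x$r_c, x$N_c, x$e_value_h, x$p_value))
  invisible(x)
}

#' Success predicate for a pipeline stage
#'
#' A stage (training, validation, or test) succeeds iff the predictions are
#' enriched (`E-value_h > 1`) and the enrichment is significant at the
#' stage's threshold (Bonferroni-corrected during training/validation, 0.05
#' at test). This single predicate is used everywhere a verdict is needed.
#'
#' @param e_value_h Set enrichment of the predictions.
#' @param p_value One-tailed Fisher p-value.
#' @param threshold Significance threshold for this stage.
#' @return Logical.
#' @export
stage_success <- function(e_value_h, p_value, threshold) {
  e_value_h > 1 & p_value < threshold
}

#' Confusion-matrix performance measures
#'
#' Sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)`, and precision
#' `TP / (TP + FP)`. A measure whose denominator is zero is undefined and
#' reported as `NA` (never 0).
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return List with `sensitivity`, `specificity`, `precision` (raw ratios)
#'   and `percent`, the same three rounded to integer percentages.
#' @export
confusion_measures <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  list(sensitivity = sens, specificity = spec, precision = prec,
       percent = c(sensitivity = round(100 * sens),
                   specificity = round(100 * spec),
                   precision = round(100 * prec)))
}

#' Overlap enrichment of a prediction set by random-subset resampling
#'
#' Measures whether the predictions overlap a reference feature set more
#' often than size-matched random subsets of the prediction pool do. Each of
#' `n_trials` trials draws `|predictions|` ids uniformly without replacement
#' from the pool and records the overlap with the reference set. The
#' expected overlap is the analytic hypergeometric mean
#' `|predictions| * |reference| / |pool|` (which the trial mean estimates);
#' the Z-score standardises the observed overlap by the trial mean and
#' standard deviation, and the p-value is the upper tail of the standard
#' normal at Z (values below double precision are reported as 0).
#'
#' @param predictions Character vector of predicted ids (a subset of
#'   `pool`).
#' @param pool Character vector: the universe the predictions were drawn
#'   from.
#' @param reference_overlappers Ids of pool members that overlap the
#'   reference features.
#' @param n_trials Number of resampling trials (default 10000).
#' @param seed Integer seed.
#' @return An `overlap_enrichment` object: `observed`, `expected`, `fold`,
#'   `z`, `p`, `trial_mean`, `trial_sd`, `n_trials`, `seed`.
#' @export
overlap_enrichment <- function(predictions, pool, reference_overlappers,
                               n_trials = 10000, seed) {
  if (!all(predictions %in% pool)) stop("predictions must be a subset of the pool")
  if (!all(reference_overlappers %in% pool)) {
    stop("reference overlappers must be a subset of the pool")
  }
  k <- length(predictions)
  n <- length(pool)
  ref <- pool %in% reference_overlappers
  observed <- sum(predictions %in% reference_overlappers)
  trials <- with_seed(seed, {
    vapply(seq_len(n_trials), function(i) sum(ref[sample.int(n, k)]),
           numeric(1))
  })
  expected <- k * sum(ref) / n
  tmean <- mean(trials)
  tsd <- stats::sd(trials)
  z <- if (tsd > 0) (observed - tmean) / tsd else NA_real_
  p <- if (is.na(z)) NA_real_ else stats::pnorm(z, lower.tail = FALSE)
  structure(list(observed = observed, expected = expected,
                 fold = if (expected > 0) observed / expected else NA_real_,
                 z = z, p = p, trial_mean = tmean, trial_sd = tsd,
                 n_trials = n_trials, seed = seed),
            class = "overlap_enrichment")
}

#' @export
print.overlap_enrichment <- function(x, ...) {
  cat(sprintf("observed %d vs expected %.1f (%.1f-fold), Z = %.1f, p = %.3g\n",
              x$observed, x$expected, x$fold, x$z, x$p))
  invisible(x)
}

#' Call interval overlaps between predictions and reference features
#'
#' A prediction is called positive iff it intersects any reference interval
#' by at least 1 bp. Both tables use 0-based half-open coordinates on the
#' same coordinate system.
#'
#' @param predicted,reference Data frames with columns `chrom`, `start`,
#'   `end` (BED-like).
#' @return Logical vector, one entry per prediction row.
#' @export
overlap_calls <- function(predicted, reference) {
  as_gr <- function(df) {
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start + 1, df$end))
  }
  if (nrow(predicted) == 0) return(logical(0))
  if (nrow(reference) == 0) return(rep(FALSE, nrow(predicted)))
  GenomicRanges::countOverlaps(as_gr(predicted), as_gr(reference),
                               minoverlap = 1L) > 0
}
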