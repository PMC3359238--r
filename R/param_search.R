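#' Default six-parameter search grid
#'
#' The six tunable parameters and their default value sets: the distance
#' constraint between the two motifs of a pair (bp), the minimum number of
#' pair occurrences in the mixed set, the width of the pair-enrichment band
#' in standard deviations above the mean, the minimum admissible set
#' enrichment, the look-ahead width k of the greedy algorithm, and the cap
#' on mixed-set candidate sequences. The full Cartesian product has
#' 6 * 2 * 5 * 2 * 3 * 3 = 1080 combinations.
#'
#' @return Named list of grid axes, in canonical order.
#' @export
default_grid_axes <- function() {
  list(max_gap = c(25, 50, 100, 150, 200, Inf),
       min_occurrence = c(7, 8),
       cap_sd = c(2, 2.5, 3, 3.5, 4),
       min_set_evalue = c(3, 5),
       k = c(1, 5, 10),
       max_mixed_candidates = c(160, 240, 320))
}

#' Build the parameter grid
#'
#' Full Cartesian product of the axes, in deterministic order: the first
#' axis varies slowest, the last fastest (odometer order over the axes as
#' listed).
#'
#' @param axes Named list of numeric axes; defaults to
#'   [default_grid_axes()]. Any subset of axes may be overridden; names
#'   must match the canonical six.
#' @return Data frame of parameter combinations with a `combo_id` column.
#' @export
build_grid <- function(axes = default_grid_axes()) {
  canonical <- names(default_grid_axes())
  if (!all(names(axes) %in% canonical)) {
    stop("unknown grid axes: ",
         paste(setdiff(names(axes), canonical), collapse = ", "))
  }
  full <- utils::modifyList(default_grid_axes(), axes)
  if (any(vapply(full, length, integer(1)) == 0)) stop("empty grid axis")
  g <- expand.grid(rev(full), stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, canonical]
  g <- cbind(combo_id = seq_len(nrow(g)), g)
  rownames(g) <- NULL
  g
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_tests`: the per-test threshold controlling the family-wise
#' error rate over the parameter combinations tried on the training and
#' validation sets.
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests (parameter combinations actually run).
#' @return The corrected threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(is_count(n_tests), n_tests >= 1, alpha > 0)
  alpha / n_tests
}

#' Bundle the train/validation/test corpora
#'
#' @param train,validation,test Each a list with named character vectors
#'   `mixed` and `control`.
#' @return A `crm_folds` object.
#' @export
crm_folds <- function(train, validation, test) {
  folds <- list(train = train, validation = validation, test = test)
  for (f in names(folds)) {
    stopifnot(is.list(folds[[f]]),
              all(c("mixed", "control") %in% names(folds[[f]])))
  }
  ids <- unlist(lapply(folds, function(f) c(names(f$mixed), names(f$control))))
  if (anyDuplicated(ids)) {
    stop("sequence ids must be unique across all folds and sets")
  }
  structure(folds, class = "crm_folds")
}

# Precompute, per fold and set, the unconstrained pair table (max_gap = Inf)
# and corpus lengths; per-combo work then reduces to a gap filter.
prep_folds <- function(folds, hits) {
  stopifnot(inherits(folds, "crm_folds"))
  lapply(folds, function(f) {
    ids_m <- names(f$mixed)
    ids_c <- names(f$control)
    hm <- hits[hits$sequence_id %in% ids_m, , drop = FALSE]
    hc <- hits[hits$sequence_id %in% ids_c, , drop = FALSE]
    list(ids_mixed = ids_m, ids_control = ids_c,
         lengths = corpus_lengths(f$mixed, f$control),
         pairs_mixed = enumerate_pairs(hm, Inf),
         pairs_control = enumerate_pairs(hc, Inf))
  })
}

filter_gap <- function(pairs, max_gap) {
  pairs[pairs$gap <= max_gap, , drop = FALSE]
}

# Score one prepared fold against a signature and classify with the frozen
# threshold; returns the stage enrichment, success verdict, and predictions.
apply_stage <- function(prep_fold, signature, threshold_model,
                        stage_threshold) {
  pairs <- rbind(filter_gap(prep_fold$pairs_mixed, signature$max_gap),
                 filter_gap(prep_fold$pairs_control, signature$max_gap))
  scored <- score_sequences(
    signature = signature, pairs = pairs,
    sequence_ids = c(prep_fold$ids_mixed, prep_fold$ids_control),
    source_set = rep(c("mixed", "control"),
                     c(length(prep_fold$ids_mixed),
                       length(prep_fold$ids_control))))
  cand <- scored[scored$n_pairs >= 1, , drop = FALSE]
  pred <- predict_crms(cand, threshold_model)
  r_m <- sum(pred$positive & pred$source_set == "mixed")
  r_c <- sum(pred$positive & pred$source_set == "control")
  enr <- enrichment_result(r_m, length(prep_fold$ids_mixed),
                           r_c, length(prep_fold$ids_control),
                           prep_fold$lengths)
  list(enrichment = enr,
       success = stage_success(enr$e_value_h, enr$p_value, stage_threshold),
       predictions = pred,
       crm_ids = pred$sequence_id[pred$positive & pred$source_set == "mixed"])
}

#' Train and validate one parameter combination
#'
#' Runs the training stage (pair statistics, the three pair-selection
#' criteria, greedy signature selection, candidate scoring, threshold fit,
#' prediction, enrichment) and then applies the frozen signature and
#' threshold to the validation fold. The test fold is never touched here;
#' it is evaluated exactly once, for the finally selected combination, by
#' [crm_mine()].
#'
#' @param combo One row of the grid from [build_grid()] (or any list with
#'   the six parameters).
#' @param prep Prepared folds (internal structure built by [crm_mine()]
#'   from the folds and hit table).
#' @param stage_threshold Significance threshold applied at the training
#'   and validation stages (Bonferroni-corrected).
#' @return List with `train`, `validation` (each: `enrichment`, `success`),
#'   `model` (`signature` + `threshold`), or an `error` field when the
#'   combination admits no signature.
#' @export
run_combo <- function(combo, prep, stage_threshold) {
  tryCatch({
    tr <- prep$train
    pm <- filter_gap(tr$pairs_mixed, combo$max_gap)
    pc <- filter_gap(tr$pairs_control, combo$max_gap)
    stats <- pair_stats(pm, pc, tr$lengths)
    enriched <- select_enriched_pairs(stats, combo$min_occurrence, combo$cap_sd)
    gres <- greedy_select(
      enriched,
      greedy_config(k = combo$k, min_set_evalue = combo$min_set_evalue,
                    max_mixed_candidates = combo$max_mixed_candidates),
      tr$lengths, max_gap = combo$max_gap)
    sig <- gres$signature

    scored_tr <- score_sequences(
      signature = sig, pairs = rbind(pm, pc),
      sequence_ids = c(tr$ids_mixed, tr$ids_control),
      source_set = rep(c("mixed", "control"),
                       c(length(tr$ids_mixed), length(tr$ids_control))))
    cand_tr <- scored_tr[scored_tr$n_pairs >= 1, , drop = FALSE]
    thr <- fit_threshold(cand_tr)
    pred_tr <- predict_crms(cand_tr, thr)
    r_m <- sum(pred_tr$positive & pred_tr$source_set == "mixed")
    r_c <- sum(pred_tr$positive & pred_tr$source_set == "control")
    enr_tr <- enrichment_result(r_m, length(tr$ids_mixed),
                                r_c, length(tr$ids_control), tr$lengths)
    train <- list(enrichment = enr_tr,
                  success = stage_success(enr_tr$e_value_h, enr_tr$p_value,
                                          stage_threshold))
    validation <- apply_stage(prep$validation, sig, thr, stage_threshold)
    list(train = train, validation = validation,
         model = list(signature = sig, threshold = thr), error = NULL)
  }, error = function(e) {
    list(train = NULL, validation = NULL, model = NULL,
         error = conditionMessage(e))
  })
}

#' Select the best parameter combination
#'
#' Among combinations that succeeded at both training and validation,
#' returns the one with the highest validation `E-value_h`
#' (`criterion = "evalue"`) or the most significant validation p-value
#' (`criterion = "pvalue"`). Ties are broken by grid order.
#'
#' @param summary Per-combo summary data frame (from [crm_mine()]).
#' @param criterion Selection criterion.
#' @return The winning `combo_id`, or `NA` if no combination passed both
#'   stages (the failure verdict).
#' @export
select_best <- function(summary, criterion = c("evalue", "pvalue")) {
  criterion <- match.arg(criterion)
  pass <- which(summary$train_success & summary$validation_success)
  if (length(pass) == 0) return(NA_integer_)
  key <- if (criterion == "evalue") {
    -summary$validation_e_value_h[pass]
  } else {
    summary$validation_p_value[pass]
  }
  summary$combo_id[pass][order(key)[1]]
}

#' Mine for CRMs: full train / validate / test orchestration
#'
#' Runs every parameter combination of the grid through training and
#' validation, applies the Bonferroni-corrected significance threshold
#' (`alpha` divided by the number of combinations actually run), selects
#' the best combination by the validation criterion, and evaluates the
#' selected model - and only that one - on the blind test fold at the
#' uncorrected `alpha`. If no combination succeeds at both training and
#' validation, the overall verdict is failure and the test fold is never
#' touched (the expected behaviour on signature-free input).
#'
#' @param folds A [crm_folds()] object.
#' @param hits Hit data frame covering all sequences (from [scan_motifs()]
#'   or [load_hits()]).
#' @param grid Parameter grid from [build_grid()].
#' @param criterion Validation selection criterion, `"evalue"` or
#'   `"pvalue"`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return A `crm_mine_result`: list with the per-combo `summary` data
#'   frame, `best_combo` (row of the grid or `NULL`), `model`, `test`
#'   stage result, `predicted_crms` (test-fold putative CRM ids),
#'   `verdict` (logical), `bonferroni`, `n_tests`.
#' @export
crm_mine <- function(folds, hits, grid = build_grid(),
                     criterion = c("evalue", "pvalue"), alpha = 0.05) {
  criterion <- match.arg(criterion)
  prep <- prep_folds(folds, hits)
  n_tests <- nrow(grid)
  bonf <- bonferroni_threshold(alpha, n_tests)

  results <- vector("list", n_tests)
  rows <- vector("list", n_tests)
  for (i in seq_len(n_tests)) {
    combo <- as.list(grid[i, , drop = FALSE])
    res <- run_combo(combo, prep, bonf)
    results[[i]] <- res
    rows[[i]] <- data.frame(
      combo_id = combo$combo_id,
      train_e_value_h = res$train$enrichment$e_value_h %||% NA_real_,
      train_p_value = res$train$enrichment$p_value %||% NA_real_,
      train_success = res$train$success %||% FALSE,
      validation_e_value_h = res$validation$enrichment$e_value_h %||% NA_real_,
      validation_p_value = res$validation$enrichment$p_value %||% NA_real_,
      validation_success = res$validation$success %||% FALSE,
      n_signature_pairs = if (is.null(res$model)) NA_integer_
                          else nrow(res$model$signature$pairs),
      error = res$error %||% "",
      stringsAsFactors = FALSE)
  }
  summary <- cbind(do.call(rbind, rows),
                   grid[, setdiff(names(grid), "combo_id")])

  best_id <- select_best(summary, criterion)
  out <- list(summary = summary, grid = grid, criterion = criterion,
              alpha = alpha, n_tests = n_tests, bonferroni = bonf,
              best_combo = NULL, model = NULL, test = NULL,
              predicted_crms = character(0), verdict = FALSE)
  if (!is.na(best_id)) {
    best <- results[[which(grid$combo_id == best_id)]]
    out$best_combo <- grid[grid$combo_id == best_id, , drop = FALSE]
    out$model <- best$model
    out$test <- apply_stage(prep$test, best$model$signature,
                            best$model$threshold, alpha)
    out$predicted_crms <- out$test$crm_ids
    out$verdict <- out$test$success
  }
  structure(out, class = "crm_mine_result")
}

#' @export
print.crm_mine_result <- function(x, ...) {
  cat("Parameter combinations run:", x$n_tests,
      sprintf("(Bonferroni threshold %.3g)\n", x$bonferroni))
  cat("Passing train+validation:",
      sum(x$summary$train_success & x$summary$validation_success), "\n")
  if (is.null(x$best_combo)) {
    cat("Verdict: FAILURE - no regulatory signature found\n")
  } else {
    cat("Best combo:", x$best_combo$combo_id,
        sprintf("(max_gap=%s, min_occ=%d, cap_sd=%.1f, min_Eh=%g, k=%d, max_cand=%d)\n",
                format(x$best_combo$max_gap), x$best_combo$min_occurrence,
                x$best_combo$cap_sd, x$best_combo$min_set_evalue,
                x$best_combo$k, x$best_combo$max_mixed_candidates))
    cat(sprintf("Test: E-value_h = %.2f, p = %.3g -> %s; %d putative CRMs\n",
                x$test$enrichment$e_value_h, x$test$enrichment$p_value,
                if (x$verdict) "SUCCESS" else "FAILURE",
                length(x$predicted_crms)))
  }
  invisible(x)
}
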