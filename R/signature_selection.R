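#' Length-normalised enrichment E-value of a candidate sequence set
#'
#' `E-value_h = (l_c / l_m) * (r_m / r_c)` where `r_m` and `r_c` are the
#' numbers of mixed-set and control-set sequences in the candidate set.
#' `r_c = 0` with `r_m > 0` yields `Inf` (a pure mixed-set candidate set);
#' `r_m = 0` yields 0.
#'
#' @param r_m,r_c Sequence counts from the mixed and control sets.
#'   Vectorised.
#' @param lengths A [corpus_lengths()] object.
#' @return Numeric vector of set E-values.
#' @export
compute_set_evalue <- function(r_m, r_c, lengths) {
  stopifnot(inherits(lengths, "corpus_lengths"))
  ratio <- lengths$l_c / lengths$l_m
  ifelse(r_m == 0, 0, ifelse(r_c == 0, Inf, ratio * r_m / r_c))
}

#' Configuration of the greedy signature selection
#'
#' @param k Look-ahead width: how many of the top enriched pairs are
#'   examined at each step (default 1).
#' @param min_set_evalue Minimum admissible set enrichment; the algorithm
#'   stops before any step that would drop `E-value_h` below it. Must be
#'   greater than 1 (default 3).
#' @param max_mixed_candidates Hard cap on the number of mixed-set sequences
#'   in the candidate set. The recommended setting is 1-5 times the number
#'   of CRMs expected in the mixed set.
#' @param max_signature_size Cap on the number of selected pairs (defaults
#'   to `max_mixed_candidates`).
#' @return A `greedy_config` object.
#' @export
greedy_config <- function(k = 1, min_set_evalue = 3, max_mixed_candidates,
                          max_signature_size = max_mixed_candidates) {
  stopifnot(is_count(k), k >= 1, min_set_evalue > 1,
            is_count(max_mixed_candidates), max_mixed_candidates >= 1,
            is_count(max_signature_size), max_signature_size >= 1)
  structure(list(k = as.integer(k), min_set_evalue = min_set_evalue,
                 max_mixed_candidates = as.integer(max_mixed_candidates),
                 max_signature_size = as.integer(max_signature_size)),
            class = "greedy_config")
}

#' Greedy co-selection of the regulatory signature and candidate set
#'
#' Starting from the enriched pairs sorted by `E-value_p` descending, the
#' algorithm repeatedly examines the top `k` remaining pairs, computes for
#' each the set enrichment `E-value_h` that the candidate set would attain
#' if the sequences containing that pair were added, and commits the pair
#' with the best hypothetical `E-value_h` (ties: higher `E-value_p`, then
#' pair-key order). The committed pair moves from the sorted list to the
#' signature and its member sequences are unioned into the candidate set.
#'
#' The three continuation criteria are tested on the hypothetical state
#' before each commit; the algorithm stops, without committing the violating
#' addition, when (1) `E-value_h` would drop below
#' `cfg$min_set_evalue`, (2) the candidate set would hold more than
#' `cfg$max_mixed_candidates` mixed-set sequences, or (3) the signature
#' would exceed `cfg$max_signature_size` pairs. It also stops when the pair
#' list is exhausted. A pair whose addition contributes no new sequences is
#' dropped from the list without consuming a signature slot. If no pair can
#' be committed at all, the error "no admissible signature" is raised.
#'
#' @param pairs Enriched pair statistics from [select_enriched_pairs()]
#'   (sorted descending by `e_value_p`, with member list columns).
#' @param cfg A [greedy_config()].
#' @param lengths A [corpus_lengths()] object of the training corpus.
#' @param max_gap The distance constraint (bp) under which the pairs were
#'   enumerated; stored in the signature for re-scoring.
#' @return List with elements `signature` (a `crm_signature`: the ordered
#'   selected pairs with their training E-values, the distance constraint,
#'   corpus lengths, and config), `candidates` (data frame `sequence_id`,
#'   `source_set`), `e_value_h`, `r_m`, `r_c`, and a per-step `trace`.
#' @export
greedy_select <- function(pairs, cfg, lengths, max_gap = Inf) {
  stopifnot(inherits(cfg, "greedy_config"), nrow(pairs) >= 1)
  P <- pairs
  H_m <- character(0)
  H_c <- character(0)
  e_h <- 0
  trace <- list()

  repeat {
    if (nrow(P) == 0) break
    committed <- FALSE
    while (nrow(P) > 0) {
      top <- utils::head(seq_len(nrow(P)), cfg$k)
      hyp <- lapply(top, function(i) {
        m <- union(H_m, P$members_mixed[[i]])
        cc <- union(H_c, P$members_control[[i]])
        list(i = i, r_m = length(m), r_c = length(cc),
             e_h = compute_set_evalue(length(m), length(cc), lengths))
      })
      eh_vals <- vapply(hyp, `[[`, numeric(1), "e_h")
      best <- hyp[[which.max(eh_vals)]] # first max: P order encodes ties
      gain <- (best$r_m + best$r_c) > (length(H_m) + length(H_c))
      if (!gain) {
        # dead step: adding this pair changes nothing; drop it and re-examine
        P <- P[-best$i, , drop = FALSE]
        next
      }
      violated <- best$e_h < cfg$min_set_evalue ||
        best$r_m > cfg$max_mixed_candidates ||
        length(trace) + 1L > cfg$max_signature_size
      if (violated) {
        if (length(trace) == 0) stop("no admissible signature")
        P <- P[0, , drop = FALSE] # stop without committing
        break
      }
      row <- P[best$i, , drop = FALSE]
      H_m <- union(H_m, row$members_mixed[[1]])
      H_c <- union(H_c, row$members_control[[1]])
      e_h <- best$e_h
      trace[[length(trace) + 1L]] <- data.frame(
        motif_a = row$motif_a, motif_b = row$motif_b,
        e_value_p = row$e_value_p, n_m = row$n_m, n_c = row$n_c,
        r_m = length(H_m), r_c = length(H_c), e_value_h = e_h,
        stringsAsFactors = FALSE)
      P <- P[-best$i, , drop = FALSE]
      committed <- TRUE
      break
    }
    if (!committed) break
  }

  if (length(trace) == 0) stop("no admissible signature")
  steps <- do.call(rbind, trace)
  steps$rank <- seq_len(nrow(steps))
  sig <- structure(list(
    pairs = steps[, c("rank", "motif_a", "motif_b", "e_value_p", "n_m", "n_c")],
    max_gap = max_gap, lengths = lengths, config = cfg), class = "crm_signature")
  candidates <- data.frame(
    sequence_id = c(H_m, H_c),
    source_set = rep(c("mixed", "control"), c(length(H_m), length(H_c))),
    stringsAsFactors = FALSE)
  list(signature = sig, candidates = candidates,
       e_value_h = e_h, r_m = length(H_m), r_c = length(H_c), trace = steps)
}

#' @export
print.crm_signature <- function(x, ...) {
  cat("Regulatory signature:", nrow(x$pairs), "motif pairs, max gap",
      x$max_gap, "bp\n")
  print(utils::head(x$pairs, 10))
  if (nrow(x$pairs) > 10) cat("...\n")
  invisible(x)
}

#' Serialise / load a signature
#'
#' The pair list is written as TSV (`rank`, `motif_a`, `motif_b`,
#' `e_value_p`) and the distance constraint, training corpus lengths, greedy
#' configuration, and (if attached) the fitted score threshold go to a JSON
#' sidecar `<path>.json` - together sufficient to re-score any FASTA.
#'
#' @param sig A `crm_signature`.
#' @param path Path of the TSV file; the sidecar is `<path>.json`.
#' @export
write_signature <- function(sig, path) {
  utils::write.table(sig$pairs[, c("rank", "motif_a", "motif_b", "e_value_p")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(max_gap = if (is.finite(sig$max_gap)) sig$max_gap else "Inf",
               lengths = unclass(sig$lengths),
               config = unclass(sig$config),
               n_m = sig$pairs$n_m, n_c = sig$pairs$n_c,
               threshold = if (!is.null(sig$threshold)) unclass(sig$threshold))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  pairs <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pairs$n_m <- meta$n_m
  pairs$n_c <- meta$n_c
  lengths <- structure(list(l_m = meta$lengths$l_m, l_c = meta$lengths$l_c),
                       class = "corpus_lengths")
  cfg <- greedy_config(k = meta$config$k,
                       min_set_evalue = meta$config$min_set_evalue,
                       max_mixed_candidates = meta$config$max_mixed_candidates,
                       max_signature_size = meta$config$max_signature_size)
  sig <- structure(list(pairs = pairs,
                        max_gap = if (identical(meta$max_gap, "Inf")) Inf
                                  else as.numeric(meta$max_gap),
                        lengths = lengths, config = cfg),
                   class = "crm_signature")
  if (!is.null(meta$threshold)) {
    sig$threshold <- structure(meta$threshold, class = "crm_threshold")
  }
  sig
}
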