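#' Enumerate co-occurring motif pairs under a distance constraint
#'
#' Emits every unordered pair of non-overlapping motif hits on the same
#' sequence separated by at most `max_gap` bp. The gap is the start of the
#' downstream hit minus the end of the upstream hit in 0-based half-open
#' coordinates, so abutting hits have gap 0 and overlapping hits are never
#' paired. Strand is ignored: motifs are paired, not stranded sites.
#' Homotypic pairs (both hits of the same motif) are legal. Each unordered
#' hit pair is emitted exactly once.
#'
#' @param hits Hit data frame as returned by [scan_motifs()] or
#'   [load_hits()].
#' @param max_gap Maximum gap in bp between the two hits (`Inf` for no
#'   constraint).
#' @return Data frame with one row per qualifying hit pair: `sequence_id`,
#'   canonical pair key (`motif_a` <= `motif_b` lexicographically),
#'   the upstream/downstream hit coordinates (`start_i`, `end_i`,
#'   `start_j`, `end_j`, `motif_i`, `motif_j`) and `gap`.
#' @export
enumerate_pairs <- function(hits, max_gap = Inf) {
  stopifnot(max_gap >= 0)
  if (nrow(hits) == 0) return(empty_pairs())
  h <- hits[order(hits$sequence_id, hits$start, hits$end), , drop = FALSE]
  parts <- split(seq_len(nrow(h)), h$sequence_id)
  res <- lapply(parts, function(idx) {
    n <- length(idx)
    if (n < 2) return(NULL)
    st <- h$start[idx]
    en <- h$end[idx]
    # hits are start-sorted: partners of hit i are a contiguous run of hits j
    # with st[j] in [en[i], en[i] + max_gap]
    lo <- findInterval(en - 1e-9, st) + 1L
    hi <- if (is.finite(max_gap)) findInterval(en + max_gap + 1e-9, st) else rep(n, n)
    cnt <- pmax(0L, hi - lo + 1L)
    if (sum(cnt) == 0) return(NULL)
    i <- rep.int(seq_len(n), cnt)
    j <- unlist(lapply(seq_len(n), function(k) {
      if (cnt[k] > 0) seq.int(lo[k], hi[k]) else integer(0)
    }), use.names = FALSE)
    data.frame(row_i = idx[i], row_j = idx[j])
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0) return(empty_pairs())
  mi <- h$motif_id[res$row_i]
  mj <- h$motif_id[res$row_j]
  out <- data.frame(sequence_id = h$sequence_id[res$row_i],
                    motif_a = pmin(mi, mj), motif_b = pmax(mi, mj),
                    motif_i = mi, motif_j = mj,
                    start_i = h$start[res$row_i], end_i = h$end[res$row_i],
                    start_j = h$start[res$row_j], end_j = h$end[res$row_j],
                    stringsAsFactors = FALSE)
  out$gap <- out$start_j - out$end_i
  rownames(out) <- NULL
  out
}

empty_pairs <- function() {
  data.frame(sequence_id = character(0), motif_a = character(0),
             motif_b = character(0), motif_i = character(0),
             motif_j = character(0), start_i = numeric(0), end_i = numeric(0),
             start_j = numeric(0), end_j = numeric(0), gap = numeric(0),
             stringsAsFactors = FALSE)
}

#' Length-normalised enrichment E-value of a motif pair
#'
#' `E-value_p = (l_c / l_m) * (n_m / n_c)`: the factor by which the pair's
#' occurrence rate per base pair in the mixed set exceeds its rate in the
#' control set. When a pair never occurs in the control set (`n_c = 0`) the
#' count is replaced by a pseudocount of 1 to keep the value finite; such
#' extreme pairs are usually removed by the outlier cap of
#' [select_enriched_pairs()] anyway. `n_m = 0` yields 0.
#'
#' @param n_m,n_c Occurrence counts (qualifying hit-pair instances) of the
#'   pair in the mixed and control sets. Vectorised.
#' @param lengths A [corpus_lengths()] object.
#' @return Numeric vector of E-values.
#' @export
compute_pair_evalue <- function(n_m, n_c, lengths) {
  stopifnot(inherits(lengths, "corpus_lengths"))
  ratio <- lengths$l_c / lengths$l_m
  n_c_adj <- ifelse(n_c == 0, 1, n_c)
  ifelse(n_m == 0, 0, ratio * n_m / n_c_adj)
}

#' Per-pair occurrence statistics over the mixed and control corpora
#'
#' Counts qualifying hit-pair instances of every observed pair key in both
#' corpora and records the member sequences (those containing at least one
#' qualifying instance), which drive the greedy candidate selection.
#'
#' @param pairs_mixed,pairs_control Pair tables from [enumerate_pairs()] for
#'   the mixed and control corpora.
#' @param lengths A [corpus_lengths()] object for the two corpora.
#' @return Data frame with columns `motif_a`, `motif_b`, `n_m`, `n_c`,
#'   `e_value_p`, `n_seq_m`, `n_seq_c` plus list columns `members_mixed`,
#'   `members_control` holding the member sequence ids.
#' @export
pair_stats <- function(pairs_mixed, pairs_control, lengths) {
  key_m <- paste(pairs_mixed$motif_a, pairs_mixed$motif_b, sep = "\r")
  key_c <- paste(pairs_control$motif_a, pairs_control$motif_b, sep = "\r")
  keys <- sort(unique(c(key_m, key_c)))
  n_m <- as.vector(table(factor(key_m, levels = keys)))
  n_c <- as.vector(table(factor(key_c, levels = keys)))
  mem_m <- lapply(split(pairs_mixed$sequence_id, factor(key_m, levels = keys)),
                  unique)
  mem_c <- lapply(split(pairs_control$sequence_id, factor(key_c, levels = keys)),
                  unique)
  ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(motif_a = ab[, 1], motif_b = ab[, 2],
                    n_m = n_m, n_c = n_c,
                    e_value_p = compute_pair_evalue(n_m, n_c, lengths),
                    n_seq_m = vapply(mem_m, length, integer(1)),
                    n_seq_c = vapply(mem_c, length, integer(1)),
                    stringsAsFactors = FALSE)
  out$members_mixed <- unname(mem_m)
  out$members_control <- unname(mem_c)
  rownames(out) <- NULL
  out
}

#' Apply the three pair-selection criteria
#'
#' Keeps pairs that (1) occur at least `min_occurrence` times in the mixed
#' set, (2) are enriched in the mixed set (`E-value_p > 1`), and (3) lie in
#' the band above the mean E-value of the enriched pairs but below
#' `cap_sd` sample standard deviations above that mean (strict on both
#' sides). The band guards against extreme, potentially outlying pairs that
#' may not generalise beyond the training corpus. The mean and standard
#' deviation are computed over the pairs surviving criteria (1) and (2).
#'
#' @param stats Pair statistics from [pair_stats()], computed on the
#'   training corpus.
#' @param min_occurrence Minimum `n_m` (default 7).
#' @param cap_sd Width of the enrichment band in standard deviations
#'   (default 3).
#' @return The retained rows of `stats`, sorted by `e_value_p` descending
#'   (ties: `n_m` descending, then pair key).
#' @export
select_enriched_pairs <- function(stats, min_occurrence = 7, cap_sd = 3) {
  surv <- stats[stats$n_m >= min_occurrence & stats$e_value_p > 1, ,
                drop = FALSE]
  if (nrow(surv) < 2) stop("no enriched pairs")
  mu <- mean(surv$e_value_p)
  sigma <- stats::sd(surv$e_value_p)
  keep <- surv$e_value_p > mu & surv$e_value_p < mu + cap_sd * sigma
  out <- surv[keep, , drop = FALSE]
  if (nrow(out) < 2) stop("no enriched pairs")
  out <- out[order(-out$e_value_p, -out$n_m, out$motif_a, out$motif_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write pair statistics as TSV
#'
#' @param stats Data frame from [pair_stats()] or
#'   [select_enriched_pairs()].
#' @param path Output path.
#' @export
write_pair_stats <- function(stats, path) {
  cols <- c("motif_a", "motif_b", "n_m", "n_c", "e_value_p",
            "n_seq_m", "n_seq_c")
  utils::write.table(stats[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
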