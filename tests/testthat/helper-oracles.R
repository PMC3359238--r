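# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check.

# Score every window of `seq` on both strands against the (already smoothed)
# probability matrix of a pwm; report hits meeting `thr`.
brute_scan <- function(seq, p, thr) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  lo <- log2(p$mat / p$background)
  W <- ncol(lo)
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(s)
  out <- list()
  if (L >= W) {
    for (i in seq_len(L - W + 1)) {
      win <- s[i:(i + W - 1)]
      for (st in c("+", "-")) {
        w <- if (st == "+") win else rev(unname(comp[win]))
        idx <- match(w, c("A", "C", "G", "T"))
        if (anyNA(idx)) next
        sc <- sum(lo[cbind(idx, seq_len(W))])
        if (sc >= thr) {
          out[[length(out) + 1]] <- data.frame(
            start = i - 1, end = i - 1 + W, strand = st, score = sc,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      strand = character(0), score = numeric(0)))
  }
  o <- do.call(rbind, out)
  o[order(o$start, o$strand), ]
}

# O(H^2) double loop over all hit pairs on one sequence.
brute_pairs <- function(hits1, max_gap) {
  n <- nrow(hits1)
  out <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        a <- hits1[i, ]
        b <- hits1[j, ]
        up <- if (a$start <= b$start) a else b
        dn <- if (a$start <= b$start) b else a
        gap <- dn$start - up$end
        if (gap >= 0 && gap <= max_gap) {
          out[[length(out) + 1]] <- data.frame(
            motif_a = min(a$motif_id, b$motif_id),
            motif_b = max(a$motif_id, b$motif_id),
            start_i = up$start, start_j = dn$start, gap = gap,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(motif_a = character(0), motif_b = character(0),
                      start_i = numeric(0), start_j = numeric(0),
                      gap = numeric(0)))
  }
  o <- do.call(rbind, out)
  o[order(o$motif_a, o$motif_b, o$start_i, o$start_j), ]
}

# Exhaustive one-tailed hypergeometric tail via binomial coefficients.
brute_fisher_greater <- function(r_m, N_m, r_c, N_c) {
  K <- r_m + r_c              # total positives (fixed margin)
  total <- N_m + N_c
  p <- 0
  for (k in r_m:min(K, N_m)) {
    p <- p + choose(N_m, k) * choose(N_c, K - k) / choose(total, K)
  }
  p
}

# Straight-order greedy baseline (k = 1): take pairs in the given order,
# skipping zero-gain pairs, until a stop criterion fires.
brute_greedy_k1 <- function(pairs, min_eh, max_mixed, max_sig, ratio) {
  H_m <- character(0)
  H_c <- character(0)
  sel <- integer(0)
  for (i in seq_len(nrow(pairs))) {
    m <- union(H_m, pairs$members_mixed[[i]])
    cc <- union(H_c, pairs$members_control[[i]])
    if (length(m) + length(cc) == length(H_m) + length(H_c)) next
    eh <- if (length(m) == 0) 0 else if (length(cc) == 0) Inf else
      ratio * length(m) / length(cc)
    if (eh < min_eh || length(m) > max_mixed || length(sel) + 1 > max_sig) break
    H_m <- m
    H_c <- cc
    sel <- c(sel, i)
  }
  list(sel = sel, H_m = H_m, H_c = H_c)
}

# A small deterministic hit table builder: hits at given (start, motif) per
# sequence, unit scores, width w.
make_hits <- function(..., w = 10) {
  specs <- list(...)
  rows <- lapply(names(specs), function(sid) {
    sp <- specs[[sid]]
    data.frame(sequence_id = sid, motif_id = sp$motif,
               start = sp$start, end = sp$start + w, strand = "+",
               score = 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Pair-stat rows with explicit member sets, for greedy tests.
pair_row <- function(a, b, e_p, n_m, n_c, mem_m, mem_c) {
  df <- data.frame(motif_a = a, motif_b = b, n_m = n_m, n_c = n_c,
                   e_value_p = e_p, n_seq_m = length(mem_m),
                   n_seq_c = length(mem_c), stringsAsFactors = FALSE)
  df$members_mixed <- list(mem_m)
  df$members_control <- list(mem_c)
  df
}

unit_lengths <- function(ratio = 5) corpus_lengths(1, ratio)
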