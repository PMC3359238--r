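#' Construct a position weight matrix object
#'
#' @param motif_id Motif identifier.
#' @param mat 4 x W matrix of per-position base probabilities, rows A, C, G,
#'   T. Each column must sum to 1 (tolerance 1e-6). Zero cells are smoothed
#'   with pseudo-probability 1e-3 and the column renormalised, so log-odds
#'   scores stay finite for any A/C/G/T window.
#' @param background Length-4 vector of background base frequencies
#'   (A, C, G, T), summing to 1. Default uniform.
#' @param score_threshold Optional log-odds (base 2) score threshold.
#' @param p_value Optional p-value threshold; converted to a score threshold
#'   at scan time via the exact score distribution of the background model
#'   (see [pwm_score_threshold()]).
#' @return A `pwm` object.
#' @export
pwm <- function(motif_id, mat, background = rep(0.25, 4),
                score_threshold = NULL, p_value = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 1) stop("PWM must have at least one column")
  if (any(abs(colSums(mat) - 1) > 1e-6)) {
    stop("PWM columns must each sum to 1")
  }
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 frequencies summing to 1")
  }
  mat[mat == 0] <- 1e-3
  mat <- sweep(mat, 2, colSums(mat), "/")
  rownames(mat) <- DNA_BASES
  structure(list(motif_id = motif_id, mat = mat,
                 background = as.numeric(background),
                 score_threshold = score_threshold, p_value = p_value),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$motif_id, "width", ncol(x$mat), "\n")
  cat("consensus:", paste(DNA_BASES[apply(x$mat, 2, which.max)], collapse = ""),
      "\n")
  invisible(x)
}

pwm_width <- function(x) ncol(x$mat)

# Log-odds (base 2) scoring matrix of a pwm.
pwm_lodds <- function(x) log2(x$mat / x$background)

# Reverse-complement scoring matrix: scoring the forward strand with this
# matrix equals scoring the reverse complement with the original.
pwm_lodds_rc <- function(x) {
  lo <- pwm_lodds(x)
  lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]
}

#' Exact score distribution and p-value-to-score conversion
#'
#' The null distribution of the window log-odds score under the background
#' model is computed by exact convolution over positions for motif widths up
#' to `max_exact_width` (scores of all 4^W words, aggregated over ties), and
#' by dynamic-programming convolution on a discretised score lattice
#' (bin 1e-3) for wider motifs. The returned threshold is the smallest score
#' t with P(score >= t) <= p under the background model; `Inf` if even the
#' maximal score is more probable than `p`.
#'
#' @param x A `pwm` object.
#' @param p_value Upper-tail probability.
#' @param max_exact_width Largest width for the exact enumeration
#'   (default 12).
#' @return Log-odds score threshold (scalar).
#' @export
pwm_score_threshold <- function(x, p_value, max_exact_width = 12) {
  stopifnot(inherits(x, "pwm"), p_value > 0)
  d <- score_distribution(pwm_lodds(x), x$background, max_exact_width)
  tail_p <- cumsum(d$prob) # d is sorted by score descending
  ok <- tail_p <= p_value + 1e-12
  if (!any(ok)) return(Inf)
  d$score[max(which(ok))]
}

# Distribution of the window score: data.frame(score, prob) sorted by score
# descending, aggregated over distinct scores.
score_distribution <- function(lodds, background, max_exact_width = 12,
                               bin = 1e-3) {
  W <- ncol(lodds)
  if (W <= max_exact_width) {
    sc <- 0
    pr <- 1
    for (j in seq_len(W)) {
      sc <- as.vector(outer(lodds[, j], sc, "+"))
      pr <- as.vector(outer(background, pr, "*"))
      # aggregate ties to keep the state space small where scores collide
      if (length(sc) > 4^9) {
        key <- round(sc, 9)
        agg <- rowsum(pr, key)
        sc <- as.numeric(rownames(agg))
        pr <- as.vector(agg)
      }
    }
    key <- round(sc, 9)
    agg <- rowsum(pr, key)
    sc <- as.numeric(rownames(agg))
    pr <- as.vector(agg)
  } else {
    # lattice DP: integerised scores, convolved column by column
    q <- round(lodds / bin)
    lo <- sum(apply(q, 2, min))
    hi <- sum(apply(q, 2, max))
    p <- numeric(hi - lo + 1)
    # start: empty prefix has score 0 at offset -lo + 1
    p[-lo + 1] <- 1
    cur_lo <- 0
    for (j in seq_len(W)) {
      nxt <- numeric(length(p))
      for (b in 1:4) {
        sh <- q[b, j]
        idx <- seq_along(p)
        src <- idx - sh
        valid <- src >= 1 & src <= length(p)
        nxt[idx[valid]] <- nxt[idx[valid]] + background[b] * p[src[valid]]
      }
      p <- nxt
    }
    nz <- which(p > 0)
    sc <- (nz - 1 + lo) * bin
    pr <- p[nz]
  }
  o <- order(sc, decreasing = TRUE)
  data.frame(score = sc[o], prob = pr[o])
}

#' Scan sequences for motif occurrences on both strands
#'
#' Every window of each sequence and its reverse complement is scored with
#' the log-odds (base 2) model of each PWM; windows meeting the motif's score
#' threshold are reported as hits. Reverse-strand hits are reported in
#' forward coordinates (0-based half-open). Windows containing any
#' non-A/C/G/T residue (e.g. N) never pass. Overlapping hits, of the same or
#' of different motifs, are all kept. Soft-masked (lowercase) residues are
#' scanned like their uppercase counterparts.
#'
#' @param seqs Named character vector of sequences.
#' @param pwms A `pwm` object or list of them.
#' @param p_value Optional p-value threshold applied to every motif lacking
#'   its own threshold (see [pwm_score_threshold()]).
#' @param score_threshold Optional log-odds threshold applied to every motif
#'   lacking its own threshold. Exactly one source of threshold must be
#'   available per motif.
#' @return Data frame with columns `sequence_id`, `motif_id`, `start`, `end`,
#'   `strand`, `score`, sorted by (sequence_id, start, motif_id, strand).
#' @export
scan_motifs <- function(seqs, pwms, p_value = NULL, score_threshold = NULL) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  stopifnot(length(seqs) >= 1, all(nzchar(names(seqs))))
  widths <- vapply(pwms, pwm_width, integer(1))
  sep <- max(widths)

  # one concatenated code vector; NA separators prevent cross-sequence windows
  chars <- strsplit(toupper(seqs), "", fixed = TRUE)
  lens <- nchar(seqs)
  codes_list <- lapply(chars, function(ch) match(ch, DNA_BASES))
  pad <- rep(NA_integer_, sep)
  codes <- unlist(lapply(codes_list, function(x) c(x, pad)), use.names = FALSE)
  starts_at <- cumsum(c(1L, utils::head(lens + sep, -1L))) # concat offset per seq
  seq_idx_of <- rep(seq_along(seqs), lens + sep)

  out <- vector("list", length(pwms) * 2L)
  k <- 0L
  for (m in pwms) {
    W <- pwm_width(m)
    thr <- m$score_threshold
    if (is.null(thr)) {
      pv <- m$p_value %||% p_value
      if (!is.null(pv)) {
        thr <- pwm_score_threshold(m, pv)
      } else {
        thr <- score_threshold
      }
    }
    if (is.null(thr)) {
      stop("no score threshold or p-value available for motif ", m$motif_id)
    }
    for (strand in c("+", "-")) {
      lo <- if (strand == "+") pwm_lodds(m) else pwm_lodds_rc(m)
      nw <- length(codes) - W + 1L
      sc <- numeric(nw)
      for (j in seq_len(W)) {
        sc <- sc + lo[, j][codes[j:(j + nw - 1L)]]
      }
      pos <- which(!is.na(sc) & sc >= thr)
      if (length(pos)) {
        si <- seq_idx_of[pos]
        local0 <- pos - starts_at[si] # 0-based start within sequence
        k <- k + 1L
        out[[k]] <- data.frame(sequence_id = names(seqs)[si],
                               motif_id = m$motif_id,
                               start = local0, end = local0 + W,
                               strand = strand, score = sc[pos],
                               stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (k) do.call(rbind, out[seq_len(k)]) else empty_hits()
  hits <- hits[order(hits$sequence_id, hits$start, hits$motif_id, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(sequence_id = character(0), motif_id = character(0),
             start = numeric(0), end = numeric(0), strand = character(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

#' Load a precomputed motif-hit table
#'
#' Ingests hits produced by an external scanner (e.g. MAST- or FIMO-derived
#' tables exported as TSV). The expected columns are `sequence_id`,
#' `motif_id`, `start`, `end`, `strand`, `score`. Coordinates are normalised
#' to 0-based half-open; input in 1-based closed convention is converted via
#' `dialect = "one_closed"`.
#'
#' @param path Path to the TSV file (with header).
#' @param dialect Coordinate convention of the input file.
#' @param seq_lengths Optional named numeric vector of sequence lengths used
#'   to validate that hits lie within their sequence.
#' @return Hit data frame sorted by (sequence_id, start).
#' @export
load_hits <- function(path, dialect = c("zero_half_open", "one_closed"),
                      seq_lengths = NULL) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  required <- c("sequence_id", "motif_id", "start", "end", "strand", "score")
  if (!all(required %in% names(df))) {
    stop("hit table must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(df) == 0) return(empty_hits())
  df <- df[, required]
  suppressWarnings({
    df$start <- as.numeric(df$start)
    df$end <- as.numeric(df$end)
    df$score <- as.numeric(df$score)
  })
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$score) |
                 !df$strand %in% c("+", "-") |
                 !nzchar(df$sequence_id) | !nzchar(df$motif_id))
  if (length(bad)) {
    stop("malformed hit table row at line ", bad[1] + 1L, " of ", path)
  }
  if (dialect == "one_closed") df$start <- df$start - 1
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop("invalid hit interval at line ", bad[1] + 1L, " of ", path)
  }
  if (!is.null(seq_lengths)) {
    len <- seq_lengths[df$sequence_id]
    bad <- which(is.na(len) | df$end > len)
    if (length(bad)) {
      stop("hit outside sequence bounds at line ", bad[1] + 1L, " of ", path)
    }
  }
  df <- df[order(df$sequence_id, df$start), ]
  rownames(df) <- NULL
  df
}

#' @rdname load_hits
#' @param hits Hit data frame.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses the letter-probability matrix blocks of a MEME minimal file into
#' `pwm` objects. The file's background letter frequencies, if present, are
#' attached to every motif; otherwise a uniform background is used.
#'
#' @param path Path to a MEME minimal file.
#' @return Named list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    freq <- vals[!is.na(vals)]
    lett <- toupper(toks[is.na(vals)])
    if (length(freq) >= 4 && all(DNA_BASES %in% lett)) {
      bg <- freq[match(DNA_BASES, lett)]
    }
  }
  motif_at <- grep("^MOTIF\\s+", lines)
  if (!length(motif_at)) stop("no MOTIF blocks found in ", path)
  pwms <- lapply(motif_at, function(i) {
    id <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[i])), "\\s+")[[1]][1]
    j <- i
    while (j <= length(lines) && !grepl("^letter-probability matrix", lines[j])) {
      j <- j + 1L
    }
    if (j > length(lines)) stop("motif ", id, " has no letter-probability matrix")
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j])))
    rows <- list()
    j <- j + 1L
    while (j <= length(lines) && length(rows) < (if (is.na(w)) Inf else w)) {
      tok <- suppressWarnings(as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]]))
      if (length(tok) != 4 || anyNA(tok)) break
      rows[[length(rows) + 1L]] <- tok
      j <- j + 1L
    }
    if (!is.na(w) && length(rows) != w) {
      stop("motif ", id, ": expected ", w, " matrix rows, found ", length(rows))
    }
    pwm(id, t(do.call(rbind, rows)), background = bg)
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "motif_id")
  pwms
}

#' Write motifs in MEME minimal format
#'
#' @param pwms Named list of `pwm` objects.
#' @param path Output path.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies"), con)
  bg <- pwms[[1]]$background
  writeLines(sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
             con)
  for (m in pwms) {
    writeLines(c("", paste("MOTIF", m$motif_id),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         pwm_width(m))), con)
    utils::write.table(format(t(m$mat), digits = 6), con, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
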