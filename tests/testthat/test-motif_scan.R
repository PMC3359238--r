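test_that("scanner agrees with the brute-force window oracle on random sequences", {
  set.seed(7)
  for (rep in 1:8) {
    W <- sample(4:8, 1)
    mat <- matrix(runif(4 * W), nrow = 4)
    mat <- sweep(mat, 2, colSums(mat), "/")
    p <- pwm("mx", mat)
    L <- sample(20:200, 1)
    seq_chars <- sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04))
    s <- setNames(paste(seq_chars, collapse = ""), "s1")
    thr <- quantile(runif(5, -3, 3), 0.5)
    p$score_threshold <- as.numeric(thr)
    got <- scan_motifs(s, p)
    want <- brute_scan(s[[1]], p, p$score_threshold)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      got <- got[order(got$start, got$strand), ]
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  }
})

test_that("single-base motif on AAA yields exactly the forward brute-force hits", {
  p <- pwm("a1", matrix(c(1, 0, 0, 0), nrow = 4), score_threshold = 0)
  got <- scan_motifs(c(s = "AAA"), p)
  want <- brute_scan("AAA", p, 0)
  expect_equal(nrow(got), nrow(want))
  expect_equal(nrow(got), 3)            # A-motif never matches on the minus strand here
  expect_true(all(got$strand == "+"))
  expect_true(all(got$score > 1.9))     # ~log2(4), shrunk slightly by smoothing
})

test_that("uniform PWM scores every window zero and palindromes hit on both strands", {
  u <- pwm("u", matrix(0.25, nrow = 4, ncol = 4), score_threshold = 0)
  got <- scan_motifs(c(s = "ACGTACGT"), u)
  expect_true(all(got$score == 0))
  expect_equal(nrow(got), 2 * (8 - 4 + 1))

  # palindromic motif: strong on ACGT which is its own reverse complement
  pal <- pwm("pal", matrix(c(.97, .01, .01, .01,
                             .01, .97, .01, .01,
                             .01, .01, .97, .01,
                             .01, .01, .01, .97), nrow = 4),
             score_threshold = 5)
  got <- scan_motifs(c(s = "ACGT"), pal)
  expect_equal(sort(got$strand), c("+", "-"))
  expect_equal(got$start, c(0, 0))
})

test_that("windows containing N never pass and short sequences yield no hits", {
  p <- pwm("a1", matrix(c(1, 0, 0, 0), nrow = 4), score_threshold = -100)
  expect_equal(nrow(scan_motifs(c(s = "ANA"), p)), 2 + 2) # both strands, N skipped
  wide <- pwm("w", matrix(0.25, nrow = 4, ncol = 10), score_threshold = -100)
  expect_equal(nrow(scan_motifs(c(s = "ACGT"), wide)), 0)
})

test_that("scanning the reverse complement mirrors coordinates and swaps strands", {
  set.seed(42)
  mat <- matrix(runif(4 * 6), nrow = 4)
  mat <- sweep(mat, 2, colSums(mat), "/")
  p <- pwm("m", mat, score_threshold = -2)
  s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  fwd <- scan_motifs(c(x = s), p)
  rev_ <- scan_motifs(c(x = rc), p)
  expect_equal(nrow(fwd), nrow(rev_))
  mirrored <- data.frame(start = nchar(s) - rev_$end,
                         strand = ifelse(rev_$strand == "+", "-", "+"),
                         score = rev_$score)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  fwd_o <- fwd[order(fwd$start, fwd$strand), ]
  expect_equal(fwd_o$start, mirrored$start)
  expect_equal(fwd_o$strand, mirrored$strand)
  expect_equal(fwd_o$score, mirrored$score, tolerance = 1e-9)
})

test_that("p-value thresholds match the exact tail of the score distribution", {
  set.seed(13)
  mat <- matrix(runif(4 * 6), nrow = 4)
  mat <- sweep(mat, 2, colSums(mat), "/")
  p <- pwm("m", mat)
  # enumerate all 4^6 words directly
  words <- as.matrix(expand.grid(rep(list(1:4), 6)))
  lo <- log2(p$mat / p$background)
  scores <- rowSums(matrix(lo[cbind(as.vector(words),
                                    rep(1:6, each = nrow(words)))],
                           nrow = nrow(words)))
  probs <- rep(1 / 4^6, nrow(words))
  for (pv in c(1e-3, 1e-2, 0.1)) {
    thr <- pwm_score_threshold(p, pv)
    expect_lte(sum(probs[scores >= thr]), pv + 1e-12)
    # next-lower distinct achievable score would exceed the p-value budget
    below <- max(scores[scores < thr - 1e-9])
    expect_gt(sum(probs[scores >= below]), pv)
  }
})

test_that("lattice and exact thresholds agree for the same motif", {
  set.seed(5)
  mat <- matrix(runif(4 * 7), nrow = 4)
  mat <- sweep(mat, 2, colSums(mat), "/")
  p <- pwm("m", mat)
  exact <- pwm_score_threshold(p, 1e-3, max_exact_width = 12)
  lattice <- pwm_score_threshold(p, 1e-3, max_exact_width = 0)
  expect_equal(exact, lattice, tolerance = 5e-3)
})

test_that("hit tables round-trip, normalise coordinates, and reject malformed rows", {
  f <- tempfile(fileext = ".tsv")
  hits <- data.frame(sequence_id = c("s2", "s1"), motif_id = c("m", "m"),
                     start = c(5, 1), end = c(10, 10),
                     strand = c("+", "-"), score = c(1, 2),
                     stringsAsFactors = FALSE)
  write_hits(hits, f)
  back <- load_hits(f)
  expect_equal(back$sequence_id, c("s1", "s2")) # sorted output
  expect_equal(back$start, c(1, 5))

  one_closed <- load_hits(f, dialect = "one_closed")
  expect_equal(one_closed$start, c(0, 4))

  expect_error(load_hits(f, seq_lengths = c(s1 = 9, s2 = 20)),
               "outside sequence bounds")

  writeLines("sequence_id\tmotif_id\tstart\tend\tstrand\tscore", f)
  expect_equal(nrow(load_hits(f)), 0)

  writeLines(c("sequence_id\tmotif_id\tstart\tend\tstrand\tscore",
               "s1\tm\tfoo\t10\t+\t1"), f)
  expect_error(load_hits(f), "line 2")
})

test_that("MEME minimal round-trip preserves matrices and background", {
  pwms <- build_motif_library(n_motifs = 3, width = 6, seed = 2)
  f <- tempfile(fileext = ".meme")
  write_meme(pwms, f)
  back <- read_meme(f)
  expect_equal(names(back), names(pwms))
  for (id in names(pwms)) {
    expect_equal(back[[id]]$mat, pwms[[id]]$mat, tolerance = 1e-4)
  }
})
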