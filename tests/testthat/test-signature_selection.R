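test_that("set E-value reproduces the published testing enrichments under the 1:5 design", {
  lens <- unit_lengths(5)
  expect_equal(round(compute_set_evalue(41, 30, lens), 1), 6.8)
  expect_equal(round(compute_set_evalue(32, 32, lens), 1), 5.0)
  expect_equal(compute_set_evalue(5, 0, lens), Inf)
  expect_equal(compute_set_evalue(0, 10, lens), 0)
})

toy_pairs <- function() {
  rbind(
    pair_row("A", "B", 10, 8, 2, paste0("m", 1:4), paste0("c", 1:2)),
    pair_row("C", "D", 8, 7, 0, paste0("m", 5:7), character(0)),
    pair_row("E", "F", 6, 7, 3, paste0("m", c(1, 8)), paste0("c", 3:4)))
}

test_that("greedy selection matches an exhaustive trace of the loop on a toy instance", {
  pairs <- toy_pairs()
  lens <- unit_lengths(5)
  cfg <- greedy_config(k = 3, min_set_evalue = 3, max_mixed_candidates = 240)
  res <- greedy_select(pairs, cfg, lens, max_gap = 50)

  # exhaustive hand-trace: step 1 examines all three pairs
  #   A-B: 4/2 -> 10;  C-D: 3/0 -> Inf;  E-F: 2/2 -> 5   => pick C-D
  #   step 2: A-B: {m1..m7}/{c1,c2} -> 5*7/2 = 17.5
  #           E-F: {m5..m7,m1,m8}/{c3,c4} -> 5*5/2 = 12.5 => pick A-B
  #   step 3: E-F: {m1..m8}/{c1..c4} -> 5*8/4 = 10 >= 3   => pick E-F
  expect_equal(res$signature$pairs$motif_a, c("C", "A", "E"))
  expect_equal(res$trace$e_value_h, c(Inf, 17.5, 10))
  expect_equal(res$r_m, 8)
  expect_equal(res$r_c, 4)
  expect_equal(res$signature$max_gap, 50)
})

test_that("a pure-mixed pair at k = 1 is selected first with infinite set enrichment", {
  pairs <- pair_row("A", "B", 9, 12, 0, paste0("m", 1:5), character(0))
  res <- greedy_select(pairs, greedy_config(k = 1, min_set_evalue = 3,
                                            max_mixed_candidates = 10),
                       unit_lengths(5))
  expect_equal(res$e_value_h, Inf)
  expect_equal(res$r_c, 0)
})

test_that("greedy stops before committing a violating addition and errors when nothing is admissible", {
  lens <- unit_lengths(5)
  # second pair would blow the mixed-candidate cap: stop with the first only
  pairs <- rbind(
    pair_row("A", "B", 10, 8, 1, paste0("m", 1:3), "c1"),
    pair_row("C", "D", 9, 8, 1, paste0("m", 4:9), "c2"))
  res <- greedy_select(pairs, greedy_config(k = 1, min_set_evalue = 2,
                                            max_mixed_candidates = 5), lens)
  expect_equal(nrow(res$signature$pairs), 1)
  expect_equal(res$r_m, 3)

  # first addition already below the minimum set enrichment -> error
  weak <- pair_row("A", "B", 10, 8, 1, "m1", paste0("c", 1:9))
  expect_error(greedy_select(weak, greedy_config(k = 1, min_set_evalue = 3,
                                                 max_mixed_candidates = 240),
                             lens),
               "no admissible signature")
})

test_that("with k = 1 the greedy equals the straight-order baseline", {
  set.seed(27)
  for (rep in 1:6) {
    n <- sample(4:12, 1)
    pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
      pair_row(sprintf("P%02d", i), sprintf("Q%02d", i),
               e_p = round(runif(1, 2, 20), 2), n_m = sample(7:20, 1),
               n_c = sample(0:10, 1),
               mem_m = paste0("m", sample(40, sample(1:8, 1))),
               mem_c = paste0("c", sample(60, sample(0:6, 1))))
    }))
    pairs <- pairs[order(-pairs$e_value_p), ]
    lens <- unit_lengths(5)
    cfg <- greedy_config(k = 1, min_set_evalue = 3, max_mixed_candidates = 25,
                         max_signature_size = 6)
    got <- tryCatch(greedy_select(pairs, cfg, lens),
                    error = function(e) NULL)
    want <- brute_greedy_k1(pairs, 3, 25, 6, ratio = 5)
    if (is.null(got)) {
      expect_length(want$sel, 0)
    } else {
      expect_equal(got$signature$pairs$motif_a, pairs$motif_a[want$sel])
      expect_setequal(got$candidates$sequence_id, c(want$H_m, want$H_c))
    }
  }
})

test_that("candidate set only grows and committed steps respect every bound", {
  set.seed(99)
  pairs <- do.call(rbind, lapply(1:10, function(i) {
    pair_row(sprintf("P%02d", i), sprintf("Q%02d", i),
             e_p = round(runif(1, 2, 15), 2), n_m = 10, n_c = 2,
             mem_m = paste0("m", sample(30, 6)),
             mem_c = paste0("c", sample(50, 3)))
  }))
  pairs <- pairs[order(-pairs$e_value_p), ]
  cfg <- greedy_config(k = 3, min_set_evalue = 3, max_mixed_candidates = 20,
                       max_signature_size = 4)
  res <- tryCatch(greedy_select(pairs, cfg, unit_lengths(5)),
                  error = function(e) NULL)
  if (!is.null(res)) {
    expect_true(all(res$trace$e_value_h >= 3))
    expect_true(all(diff(res$trace$r_m) >= 0))
    expect_true(all(diff(res$trace$r_c) >= 0))
    expect_lte(res$r_m, 20)
    expect_lte(nrow(res$signature$pairs), 4)
  }
})

test_that("signature serialisation round-trips including the threshold sidecar", {
  pairs <- toy_pairs()
  res <- greedy_select(pairs, greedy_config(k = 3, min_set_evalue = 3,
                                            max_mixed_candidates = 240),
                       unit_lengths(5), max_gap = 100)
  sig <- res$signature
  sig$threshold <- structure(list(t = 12.3, prior_mixed = 0.4,
                                  prior_control = 0.6,
                                  control_score_mean = 8, control_score_sd = 2,
                                  search_grid = c(start = 5, stop = 10,
                                                  step = 0.1)),
                             class = "crm_threshold")
  f <- tempfile(fileext = ".tsv")
  write_signature(sig, f)
  back <- read_signature(f)
  expect_equal(back$pairs$motif_a, sig$pairs$motif_a)
  expect_equal(back$pairs$e_value_p, sig$pairs$e_value_p)
  expect_equal(back$max_gap, 100)
  expect_equal(back$lengths$l_c / back$lengths$l_m, 5)
  expect_equal(back$threshold$t, 12.3)
})
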