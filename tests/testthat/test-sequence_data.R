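test_that("tissue z-score ranking matches hand-computed values and ordering", {
  expr <- rbind(
    g_spike = c(10, 2, 2, 2),   # mean 4, sample sd 4 -> z = 1.5
    g_flat  = c(3, 3, 3, 3),    # sd 0 -> undefined, ranked last
    g_mid   = c(5, 4, 4, 4),    # z = 1.5 as well (ties broken by id)
    g_low   = c(1, 5, 5, 5))    # negative z
  colnames(expr) <- paste0("t", 1:4)
  expect_warning(top <- rank_tissue_specific_genes(expr, "t1", n = 4),
                 "zero expression standard deviation")
  expect_equal(top, c("g_mid", "g_spike", "g_low", "g_flat"))

  # z of the spike gene is exactly 1.5 under the sample sd
  z <- (10 - mean(c(10, 2, 2, 2))) / sd(c(10, 2, 2, 2))
  expect_equal(z, 1.5)
  # g_mid ties g_spike at z = 1.5; resolved lexicographically
  expect_warning(top2 <- rank_tissue_specific_genes(expr, "t1", n = 2))
  expect_equal(top2, c("g_mid", "g_spike"))
})

test_that("locus boundaries are midpoints to neighbours, flank-clipped otherwise", {
  expect_equal(build_locus(c(1000, 2000), c(100, 500), c(3000, 4000)),
               c(start = 750, end = 2500))
  expect_equal(build_locus(c(50000, 60000), right_neighbor = c(70000, 80000))[["start"]],
               0) # clipped from -50000
  expect_equal(build_locus(c(5000, 10000), left_neighbor = c(100, 200))[["end"]],
               110000)
  expect_error(build_locus(c(1000, 2000), left_neighbor = c(500, 1500)),
               "overlap")
})

test_that("build_loci chains neighbours per chromosome", {
  genes <- data.frame(chrom = "chr1", start = c(1000, 3000, 9000),
                      end = c(2000, 4000, 9500),
                      gene_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  loci <- build_loci(genes, flank = 1000)
  expect_equal(loci$start, c(0, 2500, 6500))
  expect_equal(loci$end, c(2500, 6500, 10500))
})

test_that("CNE filtering enforces length, strict repeat bound, and coding subtraction", {
  half_rep <- paste0(strrep("A", 60), strrep("a", 60))   # exactly 50% repeats
  short <- strrep("G", 99)
  keep <- strrep("C", 100)
  seqs <- c(s1 = half_rep, s2 = short, s3 = keep)
  out <- filter_cnes(seqs)
  expect_equal(names(out), "s3")

  # coding interval covering the middle 150 bp of a 300 bp sequence leaves
  # two 75 bp fragments, both below the 100 bp minimum
  seqs2 <- c(cne = strrep("A", 300))
  coding <- data.frame(seq_id = "cne", start = 75, end = 225)
  expect_length(filter_cnes(seqs2, coding), 0)
  # a shorter coding cut keeps the re-filtered fragments with /1 /2 ids
  coding2 <- data.frame(seq_id = "cne", start = 100, end = 150)
  out2 <- filter_cnes(seqs2, coding2)
  expect_equal(names(out2), c("cne/1", "cne/2"))
  expect_equal(unname(nchar(out2)), c(100, 150))
})

test_that("CNE filtering is idempotent", {
  set.seed(11)
  seqs <- setNames(
    vapply(1:30, function(i) {
      paste(sample(c("A", "C", "G", "T", "a", "c"), sample(80:300, 1),
                   replace = TRUE), collapse = "")
    }, character(1)), paste0("s", 1:30))
  once <- filter_cnes(seqs)
  expect_identical(filter_cnes(once), once)
})

test_that("control matching draws ratio controls per mixed sequence from the right length bin", {
  set.seed(3)
  mixed <- setNames(c(strrep("A", 150), strrep("A", 2500)), c("m1", "m2"))
  pool_lens <- c(rep(100:199, 2), rep(2000:2600, 1))
  pool <- setNames(vapply(pool_lens, function(l) strrep("C", l), character(1)),
                   paste0("p", seq_along(pool_lens)))
  ctrl <- match_controls(mixed, pool, ratio = 5, seed = 9)
  expect_length(ctrl, 10)
  lens <- nchar(ctrl)
  expect_equal(sum(lens >= 100 & lens < 200), 5)  # bin of the 150 bp sequence
  expect_equal(sum(lens >= 2000), 5)              # long stratum

  # determinism and per-bin count invariant
  expect_identical(match_controls(mixed, pool, ratio = 5, seed = 9), ctrl)
  expect_false(identical(match_controls(mixed, pool, ratio = 5, seed = 10), ctrl))

  # exhausted bin names the bin
  small_pool <- pool[nchar(pool) < 200][1:4]
  expect_error(match_controls(mixed["m1"], small_pool, ratio = 5, seed = 1),
               "\\[100,200\\)")
})

test_that("control matching preserves the per-bin length distribution", {
  set.seed(21)
  mixed <- setNames(vapply(sample(100:900, 40, replace = TRUE),
                           function(l) strrep("A", l), character(1)),
                    paste0("m", 1:40))
  # pool repeats the mixed lengths 6 times, so every occupied bin holds at
  # least 6x the mixed count
  pool_lens <- rep(nchar(mixed), 6)
  pool <- setNames(vapply(pool_lens, function(l) strrep("C", l), character(1)),
                   paste0("p", seq_along(pool_lens)))
  binf <- function(l) floor(l / 100)
  ctrl <- match_controls(mixed, pool, ratio = 5, seed = 2)
  tb_m <- table(binf(nchar(mixed)))
  tb_c <- table(binf(nchar(ctrl)))
  expect_equal(as.vector(tb_c[names(tb_m)]), 5 * as.vector(tb_m))
})

test_that("locus split follows the floor(.5)/floor(.25)/remainder rule and partitions", {
  s4 <- split_loci(paste0("L", 1:4), seed = 1)
  expect_equal(as.vector(table(s4$fold)[c("train", "validation", "test")]),
               c(2, 1, 1))
  s93 <- split_loci(paste0("L", 1:93), seed = 5)
  expect_equal(as.vector(table(s93$fold)[c("train", "validation", "test")]),
               c(46, 23, 24))
  s154 <- split_loci(paste0("L", 1:154), seed = 5)
  expect_equal(as.vector(table(s154$fold)[c("train", "validation", "test")]),
               c(77, 38, 39))
  # partition: every locus exactly once; same seed reproduces exactly
  expect_setequal(s154$locus_id, paste0("L", 1:154))
  expect_identical(split_loci(paste0("L", 1:154), seed = 5), s154)
  expect_error(split_loci(paste0("L", 1:3), seed = 1), "at least 4")
})

test_that("FASTA round-trip preserves ids and soft-masking", {
  f <- tempfile(fileext = ".fasta")
  seqs <- c(a = "ACGTacgt", b = "NNNNACGT")
  write_sequences(seqs, f)
  back <- read_sequences(f)
  expect_identical(back, seqs)
  expect_equal(repeat_fraction(back), c(0.5, 0))
})

test_that("expression and BED readers parse their tabular formats", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\theart\tliver", "g1\t5\t1", "g2\t0\t2"), f)
  m <- read_expression(f)
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["g1", "heart"], 5)

  b <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tfeat1\t0\t+", "chr2\t0\t50"), b)
  bed <- read_bed(b)
  expect_equal(bed$chrom, c("chr1", "chr2"))
  expect_equal(bed$name, c("feat1", "."))
  writeLines("chr1\t200\t100", b)
  expect_error(read_bed(b), "malformed")
})
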