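#' Build a synthetic motif library
#'
#' Generates `n_motifs` PWMs of width `width` with a random consensus word
#' and a per-column consensus probability drawn uniformly from
#' `consensus_range` (heterogeneous columns, as in curated TF motif
#' collections); the remaining probability mass is split evenly over the
#' other three bases.
#'
#' @param n_motifs Number of motifs (default 10).
#' @param width Motif width in bp (default 10).
#' @param consensus_range Range of the per-column consensus probability.
#' @param seed Integer seed.
#' @return Named list of `pwm` objects (`M01`, `M02`, ...).
#' @export
build_motif_library <- function(n_motifs = 10, width = 10,
                                consensus_range = c(0.88, 0.99), seed = 1) {
  with_seed(seed, {
    pwms <- lapply(seq_len(n_motifs), function(i) {
      cons <- sample.int(4, width, replace = TRUE)
      cp <- stats::runif(width, consensus_range[1], consensus_range[2])
      mat <- matrix(rep((1 - cp) / 3, each = 4), nrow = 4)
      mat[cbind(cons, seq_len(width))] <- cp
      pwm(sprintf("M%02d", i), mat)
    })
    names(pwms) <- vapply(pwms, `[[`, character(1), "motif_id")
    pwms
  })
}

#' Configuration of the synthetic benchmark generator
#'
#' Describes a desk-scale dataset with the statistical structure the miner
#' assumes: gene loci contributing CRM-like sequences (carrying planted
#' co-occurring motif pairs) and plain vicinity sequences, diluted with
#' `x`-fold background sequences in the training and validation folds, and
#' contrasted against a length- and GC-matched background control pool.
#'
#' @param n_loci Number of gene loci (default 40).
#' @param seqs_per_locus Sequences contributed by each locus (default 9).
#' @param crm_fraction Fraction of each locus's sequences that are CRMs
#'   (default 1/3).
#' @param pairs_per_crm Signature pairs planted in each CRM (default 2; the
#'   miner's model assumes mixed-set candidates contain more than one
#'   enriched pair).
#' @param n_pairs Number of motif pairs in the planted signature
#'   (default 5); pairs are formed from disjoint consecutive motifs of the
#'   library.
#' @param motif_library Named list of `pwm` objects; default
#'   `build_motif_library(seed = seed)`.
#' @param max_gap Planted gaps are drawn uniformly from
#'   `[0, max_gap / 2]`, so planted pairs satisfy the distance constraint
#'   with margin (default 100).
#' @param extra_sites Additional single motif instances planted per CRM
#'   (default 2), emulating the TFBS clustering inside real CRMs.
#' @param seq_len_range Sequence length range in bp (default 300-600).
#' @param gc GC content of the background model (default 0.41, human-like).
#' @param x Noise fold: `x * l` background sequences are added to a mixed
#'   fold assembled from `l` loci (training and validation folds only; held
#'   -out test folds contain locus sequences only).
#' @param control_ratio Controls drawn per mixed sequence (default 5).
#' @param pool_ratio Background pool size per mixed sequence (default 6;
#'   must be >= `control_ratio`).
#' @param seed Master seed; every stream (split, sequences, planting,
#'   control matching) is derived from it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_loci = 40, seqs_per_locus = 9, crm_fraction = 1 / 3,
                       pairs_per_crm = 2, n_pairs = 5, motif_library = NULL,
                       max_gap = 100, extra_sites = 2,
                       seq_len_range = c(300, 600), gc = 0.41, x = 0,
                       control_ratio = 5, pool_ratio = 6, seed = 1) {
  stopifnot(n_loci >= 4, seqs_per_locus >= 1,
            crm_fraction > 0, crm_fraction <= 1,
            pairs_per_crm >= 1, n_pairs >= 1,
            max_gap >= 0, extra_sites >= 0,
            length(seq_len_range) == 2, seq_len_range[1] <= seq_len_range[2],
            gc > 0, gc < 1, x >= 0, x == floor(x),
            control_ratio >= 1, pool_ratio >= control_ratio)
  if (is.null(motif_library)) {
    motif_library <- build_motif_library(seed = seed)
  }
  if (length(motif_library) < 2 * n_pairs) {
    stop("motif library too small for ", n_pairs, " disjoint signature pairs")
  }
  ids <- names(motif_library)
  planted <- data.frame(motif_a = ids[seq(1, 2 * n_pairs, by = 2)],
                        motif_b = ids[seq(2, 2 * n_pairs, by = 2)],
                        stringsAsFactors = FALSE)
  swap <- planted$motif_a > planted$motif_b
  planted[swap, c("motif_a", "motif_b")] <- planted[swap, c("motif_b", "motif_a")]
  structure(list(n_loci = n_loci, seqs_per_locus = seqs_per_locus,
                 crm_fraction = crm_fraction, pairs_per_crm = pairs_per_crm,
                 n_pairs = n_pairs, motif_library = motif_library,
                 signature_pairs = planted, max_gap = max_gap,
                 extra_sites = extra_sites, seq_len_range = seq_len_range,
                 gc = gc, x = x, control_ratio = control_ratio,
                 pool_ratio = pool_ratio, seed = seed),
            class = "sim_config")
}

# i.i.d. background sequence at the configured GC
random_seq <- function(len, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, len, replace = TRUE, prob = probs), collapse = "")
}

# Sample one site from a PWM (per-column categorical emission)
emit_site <- function(p) {
  paste(DNA_BASES[apply(p$mat, 2, function(col) sample.int(4, 1, prob = col))],
        collapse = "")
}

place_at <- function(seq, site, start0) {
  paste0(substr(seq, 1, start0), site,
         substr(seq, start0 + nchar(site) + 1, nchar(seq)))
}

# Plant one CRM: pairs_per_crm signature pairs + extra single sites, all
# non-overlapping. Returns the sequence and the planted-pair positions.
plant_crm <- function(seq, cfg, pair_idx) {
  lib <- cfg$motif_library
  occupied <- IRanges::IRanges()
  placements <- list()
  for (pi in pair_idx) {
    pr <- cfg$signature_pairs[pi, ]
    wa <- pwm_width(lib[[pr$motif_a]])
    wb <- pwm_width(lib[[pr$motif_b]])
    gap <- sample.int(floor(cfg$max_gap / 2) + 1L, 1L) - 1L
    span <- wa + gap + wb
    ok <- FALSE
    for (try in 1:200) {
      s0 <- sample.int(nchar(seq) - span + 1L, 1L) - 1L
      cand <- IRanges::IRanges(c(s0 + 1L, s0 + wa + gap + 1L),
                               width = c(wa, wb))
      if (length(IRanges::findOverlaps(cand, occupied)) == 0) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("cannot place a signature pair: sequence too short")
    site_a <- emit_site(lib[[pr$motif_a]])
    site_b <- emit_site(lib[[pr$motif_b]])
    if (stats::runif(1) < 0.5) site_a <- revcomp(site_a)
    if (stats::runif(1) < 0.5) site_b <- revcomp(site_b)
    seq <- place_at(seq, site_a, s0)
    seq <- place_at(seq, site_b, s0 + wa + gap)
    occupied <- c(occupied, cand)
    placements[[length(placements) + 1L]] <-
      data.frame(pair = paste(pr$motif_a, pr$motif_b, sep = "|"),
                 start_a = s0, start_b = s0 + wa + gap,
                 stringsAsFactors = FALSE)
  }
  for (e in seq_len(cfg$extra_sites)) {
    m <- lib[[sample.int(length(lib), 1L)]]
    w <- pwm_width(m)
    for (try in 1:50) {
      s0 <- sample.int(nchar(seq) - w + 1L, 1L) - 1L
      cand <- IRanges::IRanges(s0 + 1L, width = w)
      if (length(IRanges::findOverlaps(cand, occupied)) == 0) {
        site <- emit_site(m)
        if (stats::runif(1) < 0.5) site <- revcomp(site)
        seq <- place_at(seq, site, s0)
        occupied <- c(occupied, cand)
        break
      }
    }
  }
  list(seq = seq, placements = do.call(rbind, placements))
}

#' Generate a synthetic planted benchmark
#'
#' Produces a mixed corpus (CRM-like sequences with planted co-occurring
#' motif pairs, plain locus sequences, and x-fold background dilution of
#' the training and validation folds), a background control pool that is
#' length- and GC-matched by construction, ground truth, and a locus-based
#' fold assignment. All sequences are synthetic i.i.d. background outside
#' the planted sites; this is a stand-in for real genomic controls and is
#' labelled as such. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional directory; when given, writes `mixed.fasta`,
#'   `control_pool.fasta`, `truth.tsv`, and `motifs.meme` there.
#' @return A `crm_benchmark`: list with `cfg`, `mixed` (named vector, all
#'   folds), `control_pool`, `truth` (data frame `sequence_id`, `fold`,
#'   `locus_id`, `is_crm`, `pair`, `start_a`, `start_b`), `split`
#'   (locus-fold table), and `pwms`.
#' @export
generate_benchmark <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- derive_seeds(cfg$seed, 3)
  loci <- sprintf("L%03d", seq_len(cfg$n_loci))
  split <- split_loci(loci, seeds[1])
  fold_of <- stats::setNames(split$fold, split$locus_id)
  n_crm_locus <- round(cfg$seqs_per_locus * cfg$crm_fraction)

  with_seed(seeds[2], {
    mixed <- character(0)
    truth <- list()
    crm_counter <- 0L
    for (L in loci) {
      for (s in seq_len(cfg$seqs_per_locus)) {
        id <- sprintf("%s_s%02d", L, s)
        len <- sample(cfg$seq_len_range[1]:cfg$seq_len_range[2], 1L)
        sq <- random_seq(len, cfg$gc)
        is_crm <- s <= n_crm_locus
        if (is_crm) {
          # balanced round-robin over signature pairs keeps per-pair counts even
          pair_idx <- 1L + (crm_counter * cfg$pairs_per_crm +
                              seq_len(cfg$pairs_per_crm) - 1L) %% cfg$n_pairs
          crm_counter <- crm_counter + 1L
          planted <- plant_crm(sq, cfg, unique(pair_idx))
          sq <- planted$seq
          pl <- planted$placements
          truth[[length(truth) + 1L]] <- data.frame(
            sequence_id = id, fold = unname(fold_of[L]), locus_id = L,
            is_crm = TRUE, pair = pl$pair, start_a = pl$start_a,
            start_b = pl$start_b, stringsAsFactors = FALSE)
        } else {
          truth[[length(truth) + 1L]] <- data.frame(
            sequence_id = id, fold = unname(fold_of[L]), locus_id = L,
            is_crm = FALSE, pair = NA_character_, start_a = NA_real_,
            start_b = NA_real_, stringsAsFactors = FALSE)
        }
        mixed[id] <- sq
      }
    }
    # x-fold background dilution of the train and validation folds
    if (cfg$x > 0) {
      for (f in c("train", "validation")) {
        n_f <- sum(split$fold == f)
        for (b in seq_len(cfg$x * n_f)) {
          id <- sprintf("bg_%s_%04d", f, b)
          len <- sample(cfg$seq_len_range[1]:cfg$seq_len_range[2], 1L)
          mixed[id] <- random_seq(len, cfg$gc)
          truth[[length(truth) + 1L]] <- data.frame(
            sequence_id = id, fold = f, locus_id = NA_character_,
            is_crm = FALSE, pair = NA_character_, start_a = NA_real_,
            start_b = NA_real_, stringsAsFactors = FALSE)
        }
      }
    }
  })

  pool <- with_seed(seeds[3], {
    lens <- rep(nchar(mixed), each = cfg$pool_ratio)
    p <- vapply(lens, random_seq, character(1), gc = cfg$gc)
    names(p) <- sprintf("pool_%05d", seq_along(p))
    p
  })

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  bench <- structure(list(cfg = cfg, mixed = mixed, control_pool = pool,
                          truth = truth, split = split,
                          pwms = cfg$motif_library),
                     class = "crm_benchmark")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_sequences(mixed, file.path(dir, "mixed.fasta"))
    write_sequences(pool, file.path(dir, "control_pool.fasta"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_meme(cfg$motif_library, file.path(dir, "motifs.meme"))
  }
  bench
}

#' Generate a signature-free (null) dataset
#'
#' Both the pseudo-mixed set and the control pool are drawn from the same
#' background model, with no planted motif pairs: the pipeline is expected
#' to return a failure verdict on such input. Sequence and pool streams are
#' derived from disjoint sub-seeds, so the two sets never share a sequence.
#'
#' @inheritParams generate_benchmark
#' @return A `crm_benchmark` whose `truth$is_crm` is all `FALSE`.
#' @export
make_null <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- derive_seeds(cfg$seed, 3)
  loci <- sprintf("L%03d", seq_len(cfg$n_loci))
  split <- split_loci(loci, seeds[1])
  fold_of <- stats::setNames(split$fold, split$locus_id)

  mixed <- with_seed(seeds[2], {
    out <- character(0)
    for (L in loci) {
      for (s in seq_len(cfg$seqs_per_locus)) {
        len <- sample(cfg$seq_len_range[1]:cfg$seq_len_range[2], 1L)
        out[sprintf("%s_s%02d", L, s)] <- random_seq(len, cfg$gc)
      }
    }
    if (cfg$x > 0) {
      for (f in c("train", "validation")) {
        n_f <- sum(split$fold == f)
        for (b in seq_len(cfg$x * n_f)) {
          len <- sample(cfg$seq_len_range[1]:cfg$seq_len_range[2], 1L)
          out[sprintf("bg_%s_%04d", f, b)] <- random_seq(len, cfg$gc)
        }
      }
    }
    out
  })
  pool <- with_seed(seeds[3], {
    lens <- rep(nchar(mixed), each = cfg$pool_ratio)
    p <- vapply(lens, random_seq, character(1), gc = cfg$gc)
    names(p) <- sprintf("pool_%05d", seq_along(p))
    p
  })
  locus_of <- sub("_s\\d+$", "", names(mixed))
  locus_of[!locus_of %in% loci] <- NA_character_
  fold <- ifelse(is.na(locus_of),
                 sub("^bg_([a-z]+)_.*$", "\\1", names(mixed)),
                 unname(fold_of[locus_of]))
  truth <- data.frame(sequence_id = names(mixed), fold = fold,
                      locus_id = locus_of, is_crm = FALSE,
                      pair = NA_character_, start_a = NA_real_,
                      start_b = NA_real_, stringsAsFactors = FALSE)
  bench <- structure(list(cfg = cfg, mixed = mixed, control_pool = pool,
                          truth = truth, split = split,
                          pwms = cfg$motif_library),
                     class = "crm_benchmark")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_sequences(mixed, file.path(dir, "pseudo_mixed.fasta"))
    write_sequences(pool, file.path(dir, "control_pool.fasta"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  bench
}

#' Assemble train/validation/test folds from a benchmark
#'
#' Partitions the mixed sequences by their locus fold assignment and draws
#' a length-matched control set for each fold from the shared background
#' pool (without replacement across folds) via [match_controls()].
#'
#' @param bench A `crm_benchmark`.
#' @return A [crm_folds()] object.
#' @export
benchmark_folds <- function(bench) {
  stopifnot(inherits(bench, "crm_benchmark"))
  seeds <- derive_seeds(bench$cfg$seed + 7L, 3)
  fold_of <- stats::setNames(bench$truth$fold, bench$truth$sequence_id)
  pool_left <- bench$control_pool
  folds <- list()
  for (i in seq_along(c("train", "validation", "test"))) {
    f <- c("train", "validation", "test")[i]
    ids <- names(bench$mixed)[fold_of[names(bench$mixed)] == f]
    ctrl <- match_controls(bench$mixed[ids], pool_left,
                           ratio = bench$cfg$control_ratio, seed = seeds[i])
    pool_left <- pool_left[setdiff(names(pool_left), names(ctrl))]
    folds[[f]] <- list(mixed = bench$mixed[ids], control = ctrl)
  }
  crm_folds(folds$train, folds$validation, folds$test)
}

#' Desk-scale parameter grid
#'
#' A reduced grid (8 combinations) spanning the axes that matter most at
#' desk scale: two distance constraints, two enrichment-band widths, and
#' two greedy look-ahead widths. Used by the worked examples and the
#' benchmark runs; the full grid of [default_grid_axes()] remains available
#' for real corpora.
#'
#' @return Grid data frame from [build_grid()].
#' @export
desk_grid <- function() {
  build_grid(list(max_gap = c(50, 100), min_occurrence = 7,
                  cap_sd = c(2, 4), min_set_evalue = 3, k = c(1, 5),
                  max_mixed_candidates = 160))
}

#' Run the full pipeline on a synthetic benchmark
#'
#' Scans the benchmark sequences with its motif library, assembles folds,
#' runs [crm_mine()], and - when ground truth contains planted CRMs -
#' evaluates the test-fold predictions against truth (true-positive count,
#' precision, no-skill precision) and the recovered fraction of planted
#' signature pairs.
#'
#' @param bench A `crm_benchmark`.
#' @param grid Parameter grid (default [desk_grid()]).
#' @param p_value PWM scan p-value threshold (default 3e-4; the hit density
#'   that makes desk-scale pair statistics informative, see the vignette).
#' @param criterion Validation selection criterion.
#' @param alpha Family-wise error rate.
#' @return A `crm_benchmark_result`: the `crm_mine_result` plus `truth_eval`
#'   (list with `tp`, `n_predictions`, `precision`, `no_skill`,
#'   `recovered_pairs`, `n_planted_pairs`) when truth is informative.
#' @export
run_benchmark <- function(bench, grid = desk_grid(), p_value = 3e-4,
                          criterion = "pvalue", alpha = 0.05) {
  stopifnot(inherits(bench, "crm_benchmark"))
  folds <- benchmark_folds(bench)
  all_seqs <- c(bench$mixed, unlist(unname(lapply(folds, `[[`, "control"))))
  all_seqs <- all_seqs[!duplicated(names(all_seqs))]
  hits <- scan_motifs(all_seqs, bench$pwms, p_value = p_value)
  res <- crm_mine(folds, hits, grid = grid, criterion = criterion,
                  alpha = alpha)
  out <- list(mine = res, folds = folds, hits = hits)
  if (any(bench$truth$is_crm)) {
    crm_ids <- unique(bench$truth$sequence_id[bench$truth$is_crm])
    test_ids <- names(folds$test$mixed)
    pred <- res$predicted_crms
    tp <- sum(pred %in% crm_ids)
    no_skill <- sum(test_ids %in% crm_ids) / length(test_ids)
    planted <- unique(paste(bench$cfg$signature_pairs$motif_a,
                            bench$cfg$signature_pairs$motif_b, sep = "|"))
    recovered <- if (!is.null(res$model)) {
      sig_keys <- paste(res$model$signature$pairs$motif_a,
                        res$model$signature$pairs$motif_b, sep = "|")
      mean(planted %in% sig_keys)
    } else {
      0
    }
    out$truth_eval <- list(
      tp = tp, n_predictions = length(pred),
      precision = if (length(pred) > 0) tp / length(pred) else NA_real_,
      no_skill = no_skill, recovered_pairs = recovered,
      n_planted_pairs = length(planted))
  }
  structure(out, class = "crm_benchmark_result")
}
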