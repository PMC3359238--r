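#' Read sequences from a FASTA file
#'
#' Sequences are returned as a named character vector. Case is preserved:
#' lowercase residues are interpreted as soft-masked repeats throughout the
#' package (the common convention of genome FASTA distributions), so the
#' repeat content of a sequence can be recovered with [repeat_fraction()].
#'
#' @param path Path to a (possibly soft-masked) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(seqs))) {
    stop("duplicated sequence ids in ", path)
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Fraction of soft-masked (lowercase) residues per sequence
#'
#' @param seqs Named character vector of sequences.
#' @return Numeric vector of repeat fractions in `[0, 1]`.
#' @export
repeat_fraction <- function(seqs) {
  n <- nchar(seqs)
  n_upper <- nchar(gsub("[a-z]", "", seqs))
  out <- ifelse(n > 0, (n - n_upper) / n, 0)
  unname(out)
}

#' Total sequence length of the mixed and control corpora
#'
#' The two totals normalise every enrichment E-value in the package: a motif
#' pair (or candidate set) is called enriched when its rate per base pair in
#' the mixed set exceeds the rate in the control set.
#'
#' @param mixed,control Named character vectors of sequences, or numeric
#'   vectors of sequence lengths.
#' @return A `corpus_lengths` object: list with elements `l_m` and `l_c`.
#' @export
corpus_lengths <- function(mixed, control) {
  l_m <- if (is.character(mixed)) sum(nchar(mixed)) else sum(mixed)
  l_c <- if (is.character(control)) sum(nchar(control)) else sum(control)
  if (l_m <= 0 || l_c <= 0) stop("corpus lengths must be positive")
  structure(list(l_m = as.numeric(l_m), l_c = as.numeric(l_c)),
            class = "corpus_lengths")
}

#' Rank tissue-specific genes by expression z-score
#'
#' For each gene the expression level in the target tissue is standardised
#' against the gene's expression across all tissues:
#' \eqn{s_g = (e_g - mean_g) / std_g}. Genes are ranked by \eqn{s_g} in
#' descending order and the top `n` returned. Genes whose expression is
#' constant across tissues have an undefined z-score; they are flagged with a
#' warning and placed after all ranked genes.
#'
#' @param expr Numeric matrix (or data frame) of expression levels, genes in
#'   rows (rownames are gene ids), tissues in columns.
#' @param tissue Column name of the target tissue.
#' @param n Number of genes to return (default: all).
#' @param sd_method `"sample"` (n-1 denominator, the default) or
#'   `"population"`.
#' @return Character vector of the top `n` gene ids.
#' @export
rank_tissue_specific_genes <- function(expr, tissue, n = nrow(expr),
                                       sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("expression matrix must have at least 2 tissues")
  if (!tissue %in% colnames(expr)) stop("unknown tissue: ", tissue)
  if (is.null(rownames(expr))) stop("expression matrix must have gene ids as rownames")
  if (!is_count(n) || n > nrow(expr)) stop("n must be a count <= number of genes")

  mu <- rowMeans(expr)
  dev <- expr - mu
  denom <- if (sd_method == "sample") ncol(expr) - 1L else ncol(expr)
  sdv <- sqrt(rowSums(dev^2) / denom)
  z <- dev[, tissue] / sdv
  flat <- sdv == 0
  if (any(flat)) {
    warning(sum(flat), " gene(s) with zero expression standard deviation ",
            "excluded from z-ranking: ",
            paste(utils::head(rownames(expr)[flat], 5), collapse = ", "))
    z[flat] <- -Inf # ranked after all genes with a defined z-score
  }
  ids <- rownames(expr)
  ord <- order(-z, ids)
  ids[ord][seq_len(n)]
}

#' Read a gene-by-tissue expression table
#'
#' Expects a TSV with a header row: first column gene id, one column per
#' tissue.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene ids as rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Build a gene locus from a gene and its flanking neighbours
#'
#' The locus boundaries are the midpoints between the gene and each flanking
#' gene. A missing neighbour (first or last gene on the chromosome) is
#' replaced by a fixed flank of `flank` bp beyond the gene boundary, clipped
#' at coordinate 0. All coordinates are 0-based half-open.
#'
#' @param gene Numeric vector `c(start, end)` of the gene.
#' @param left_neighbor,right_neighbor Optional `c(start, end)` of the
#'   neighbouring genes; must not overlap the gene.
#' @param flank Flank size in bp used when a neighbour is missing
#'   (default 100000).
#' @return Numeric vector `c(start, end)` of the locus.
#' @export
build_locus <- function(gene, left_neighbor = NULL, right_neighbor = NULL,
                        flank = 100000) {
  stopifnot(length(gene) == 2, gene[1] < gene[2])
  if (!is.null(left_neighbor)) {
    stopifnot(length(left_neighbor) == 2, left_neighbor[1] < left_neighbor[2])
    if (left_neighbor[2] > gene[1]) {
      stop("left neighbor overlaps or is not upstream of the gene")
    }
    start <- floor((left_neighbor[2] + gene[1]) / 2)
  } else {
    start <- max(0, gene[1] - flank)
  }
  if (!is.null(right_neighbor)) {
    stopifnot(length(right_neighbor) == 2, right_neighbor[1] < right_neighbor[2])
    if (right_neighbor[1] < gene[2]) {
      stop("right neighbor overlaps or is not downstream of the gene")
    }
    end <- floor((gene[2] + right_neighbor[1]) / 2)
  } else {
    end <- gene[2] + flank
  }
  c(start = start, end = end)
}

#' Build loci for a table of genes
#'
#' Applies [build_locus()] to every gene, per chromosome, using the adjacent
#' genes (by start coordinate) as neighbours.
#'
#' @param genes Data frame with columns `chrom`, `start`, `end`, `gene_id`
#'   (BED-like, 0-based half-open) and optionally `strand`.
#' @param flank Flank for chromosome-terminal genes.
#' @return Data frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
build_loci <- function(genes, flank = 100000) {
  stopifnot(all(c("chrom", "start", "end", "gene_id") %in% names(genes)))
  out <- lapply(split(genes, genes$chrom), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    n <- nrow(g)
    loci <- lapply(seq_len(n), function(i) {
      build_locus(c(g$start[i], g$end[i]),
                  left_neighbor = if (i > 1) c(g$start[i - 1], g$end[i - 1]),
                  right_neighbor = if (i < n) c(g$start[i + 1], g$end[i + 1]),
                  flank = flank)
    })
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               start = vapply(loci, `[[`, numeric(1), 1),
               end = vapply(loci, `[[`, numeric(1), 2),
               strand = if ("strand" %in% names(g)) g$strand else "+",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Filter conserved non-coding elements
#'
#' Applies the CNE processing rules: coding intervals are cut out of each
#' sequence and the remaining non-coding fragments kept (fragment ids receive
#' "/1", "/2", ... suffixes); sequences shorter than `min_len` bp are
#' discarded; sequences whose soft-masked (lowercase) repeat fraction is not
#' strictly below `max_repeat_frac` are discarded. The operation is
#' idempotent.
#'
#' @param seqs Named character vector of sequences.
#' @param coding Optional data frame of coding intervals in sequence-local
#'   0-based half-open coordinates, columns `seq_id`, `start`, `end`.
#' @param min_len Minimum sequence length in bp (default 100).
#' @param max_repeat_frac Maximum tolerated repeat fraction, exclusive
#'   (default 0.5).
#' @return Named character vector of the retained sequences/fragments.
#' @export
filter_cnes <- function(seqs, coding = NULL, min_len = 100,
                        max_repeat_frac = 0.5) {
  if (!is.null(coding) && nrow(coding) > 0) {
    stopifnot(all(c("seq_id", "start", "end") %in% names(coding)))
    cut_ids <- intersect(names(seqs), unique(coding$seq_id))
    pieces <- lapply(names(seqs), function(id) {
      s <- seqs[[id]]
      if (!id %in% cut_ids) {
        out <- s
        names(out) <- id
        return(out)
      }
      cc <- coding[coding$seq_id == id, , drop = FALSE]
      full <- IRanges::IRanges(1L, nchar(s))
      cod <- IRanges::IRanges(pmax(cc$start, 0) + 1L, pmin(cc$end, nchar(s)))
      keep <- IRanges::setdiff(full, IRanges::reduce(cod))
      if (length(keep) == 0) return(character(0))
      frags <- substring(s, IRanges::start(keep), IRanges::end(keep))
      names(frags) <- if (length(frags) == 1 &&
                          IRanges::width(keep)[1] == nchar(s)) {
        id
      } else {
        paste0(id, "/", seq_along(frags))
      }
      frags
    })
    seqs <- unlist(pieces)
  }
  if (length(seqs) == 0) return(character(0))
  keep <- nchar(seqs) >= min_len & repeat_fraction(seqs) < max_repeat_frac
  seqs[keep]
}

#' Length-matched sampling of control sequences
#'
#' For every mixed sequence, `ratio` control sequences are drawn uniformly
#' without replacement from the pool stratum holding sequences of the same
#' 100 bp length range (e.g. a 150 bp mixed sequence is matched against pool
#' sequences of 100-199 bp). Mixed sequences of `long_cut` bp or more are
#' matched against the single stratum of pool sequences of at least
#' `long_cut` bp. Sampling is reproducible under `seed`.
#'
#' @param mixed Named character vector of mixed sequences (or numeric named
#'   vector of lengths).
#' @param pool Named character vector of candidate control sequences.
#' @param ratio Controls drawn per mixed sequence (default 5).
#' @param bin Width of the length strata in bp (default 100).
#' @param long_cut Lengths at or above this value form one open-ended stratum
#'   (default 2000).
#' @param seed Integer seed.
#' @return Named character vector: the selected control sequences.
#' @export
match_controls <- function(mixed, pool, ratio = 5, bin = 100, long_cut = 2000,
                           seed) {
  len_of <- function(x) if (is.character(x)) nchar(x) else as.numeric(x)
  lm <- len_of(mixed)
  lp <- len_of(pool)
  bin_of <- function(l) ifelse(l >= long_cut, paste0(">=", long_cut),
                               sprintf("[%d,%d)", floor(l / bin) * bin,
                                       floor(l / bin) * bin + bin))
  mb <- bin_of(lm)
  pb <- bin_of(lp)
  need <- table(mb) * ratio
  picked <- with_seed(seed, {
    unlist(lapply(names(need), function(b) {
      cand <- names(pool)[pb == b]
      if (length(cand) < need[[b]]) {
        stop("control pool exhausted in length bin ", b, ": need ",
             need[[b]], ", have ", length(cand))
      }
      sample(cand, need[[b]])
    }))
  })
  pool[picked]
}

#' Partition loci into training, validation, and test folds
#'
#' A random permutation of the loci under `seed` is split 50% / 25% / 25%:
#' the first `floor(n/2)` loci form the training fold, the next
#' `floor(n/4)` the validation fold, and the remainder the test fold.
#'
#' @param locus_ids Character vector of locus identifiers.
#' @param seed Integer seed.
#' @return Data frame with columns `locus_id` and `fold`
#'   (train/validation/test), one row per locus.
#' @export
split_loci <- function(locus_ids, seed) {
  n <- length(locus_ids)
  if (n < 4) stop("need at least 4 loci to split")
  if (anyDuplicated(locus_ids)) stop("locus ids must be unique")
  perm <- with_seed(seed, sample(locus_ids))
  n_tr <- floor(n / 2)
  n_va <- floor(n / 4)
  fold <- rep(c("train", "validation", "test"), c(n_tr, n_va, n - n_tr - n_va))
  data.frame(locus_id = perm, fold = fold, stringsAsFactors = FALSE)
}

#' Read/write a BED6-like interval table
#'
#' Minimal BED reader for the interval inputs the package consumes (gene
#' models, coding regions, reference features): the first six columns are
#' interpreted as `chrom`, `start`, `end`, `name`, `score`, `strand`;
#' missing trailing columns are filled with defaults.
#'
#' @param path Path to a tab-separated BED file without header.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  defaults <- list(NA_character_, NA_real_, NA_real_, ".", 0, "+")
  for (i in seq_along(cols)) {
    if (ncol(df) < i) df[[i]] <- defaults[[i]]
  }
  df <- df[, 1:6]
  names(df) <- cols
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$name[is.na(df$name) | df$name == ""] <- "."
  df$score[is.na(df$score)] <- 0
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  if (any(is.na(df$start) | is.na(df$end) | df$start >= df$end)) {
    stop("malformed BED intervals in ", path)
  }
  df
}

#' @rdname read_bed
#' @param x Data frame as returned by [read_bed()] (columns beyond the first
#'   three are optional).
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  utils::write.table(x[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
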