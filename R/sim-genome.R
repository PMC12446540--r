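#' Generate a synthetic genome with a replication-timing program
#'
#' Builds a binned genome whose per-bin timing value emulates the early/late
#' replication domain structure of a real genome: per chromosome, standard
#' normal noise is smoothed with a centered moving average of width
#' `config$rt_smoothness` bins (the domain length scale) and the smoothed
#' sequence is rank-rescaled genome-wide to [0, 1], with 1 = earliest
#' replicating. Optional constitutive CNV segments set the baseline copy
#' number of contiguous bin runs away from the diploid 2. Genes are placed
#' uniformly inside chromosomes.
#'
#' @param config A [sim_config()].
#' @param n_chrom Number of chromosomes.
#' @param bins_per_chrom Bins per chromosome (same for all chromosomes).
#' @param bin_size Bin width in bp (default 200000, matching 200 kb RT bins).
#' @param n_genes Number of genes to place (default 2000).
#' @param cnv Optional data.frame (chrom, start_bin, end_bin, copy) of
#'   constitutive CNV segments, 1-based inclusive bin indices per chromosome;
#'   or an integer: that many random segments with copy drawn from
#'   `cnv_copies`.
#' @param cnv_len_bins Length of random CNV segments, in bins.
#' @param cnv_copies Copy numbers random segments are drawn from.
#' @param seed Optional seed; defaults to `config$seed`. Pass `NULL` to use
#'   the current RNG state.
#'
#' @return A `genome_model`: list with `bins` (data.frame chrom, start, end,
#'   timing, copy), `genes` (data.frame gene_id, chrom, start, end, length,
#'   baseline_log2fpkm), `bin_size`, `chrom_names`, `chrom_sizes`.
#' @export
#' @examples
#' g <- make_genome(sim_config(seed = 1), n_chrom = 2, bins_per_chrom = 100)
#' range(g$bins$timing)
make_genome <- function(config,
                        n_chrom = 2L,
                        bins_per_chrom = 500L,
                        bin_size = 200000L,
                        n_genes = 2000L,
                        cnv = NULL,
                        cnv_len_bins = 20L,
                        cnv_copies = c(1L, 3L),
                        seed = config$seed) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  assert_that(is_count(n_chrom) && is_count(bins_per_chrom) && is_count(bin_size),
              "n_chrom, bins_per_chrom and bin_size must be positive integers")
  assert_that(bins_per_chrom >= 2L * config$rt_smoothness,
              "bins_per_chrom must be >= 2 * rt_smoothness")
  with_seed(seed)

  chrom_names <- paste0("chr", seq_len(n_chrom))
  k <- config$rt_smoothness
  smooth_one <- function(n) {
    z <- stats::rnorm(n + k - 1L)
    # centered moving average of width k; k = 1 leaves the noise untouched
    as.numeric(stats::filter(z, rep(1 / k, k), sides = 1L))[k:(n + k - 1L)]
  }
  raw <- unlist(lapply(chrom_names, function(cn) smooth_one(bins_per_chrom)))
  n_bins <- length(raw)
  timing <- (rank(raw, ties.method = "first") - 1) / (n_bins - 1)

  starts <- rep(seq_len(bins_per_chrom) - 1L, times = n_chrom) * bin_size
  bins <- data.frame(
    chrom = rep(chrom_names, each = bins_per_chrom),
    start = starts,
    end = starts + bin_size,
    timing = timing,
    copy = rep(2L, n_bins),
    stringsAsFactors = FALSE
  )

  if (!is.null(cnv)) {
    if (is.numeric(cnv) && length(cnv) == 1L) {
      n_seg <- as.integer(cnv)
      seg_chrom <- sample(chrom_names, n_seg, replace = TRUE)
      seg_start <- vapply(seg_chrom, function(cn)
        sample.int(bins_per_chrom - cnv_len_bins + 1L, 1L), integer(1))
      cnv <- data.frame(
        chrom = seg_chrom,
        start_bin = seg_start,
        end_bin = pmin(seg_start + cnv_len_bins - 1L, bins_per_chrom),
        copy = sample(cnv_copies, n_seg, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    assert_that(all(cnv$copy >= 1), "CNV copy numbers must be >= 1")
    for (i in seq_len(nrow(cnv))) {
      idx <- which(bins$chrom == cnv$chrom[i])[cnv$start_bin[i]:cnv$end_bin[i]]
      bins$copy[idx] <- as.integer(cnv$copy[i])
    }
  }

  chrom_sizes <- stats::setNames(rep(bins_per_chrom * bin_size, n_chrom),
                                 chrom_names)
  genes <- NULL
  if (n_genes > 0) {
    gene_chrom <- sample(chrom_names, n_genes, replace = TRUE)
    gene_len <- pmax(1000L, as.integer(round(stats::rlnorm(n_genes, log(20000), 0.6))))
    max_start <- chrom_sizes[gene_chrom] - gene_len
    gene_start <- as.integer(floor(stats::runif(n_genes, 0, pmax(1, max_start))))
    genes <- data.frame(
      gene_id = sprintf("gene%05d", seq_len(n_genes)),
      chrom = gene_chrom,
      start = gene_start,
      end = gene_start + gene_len,
      length = gene_len,
      baseline_log2fpkm = stats::rnorm(n_genes, 2, 1),
      stringsAsFactors = FALSE
    )
    ord <- order(match(genes$chrom, chrom_names), genes$start)
    genes <- genes[ord, , drop = FALSE]
    rownames(genes) <- NULL
  }

  structure(list(
    chrom_names = chrom_names,
    chrom_sizes = chrom_sizes,
    bin_size = as.integer(bin_size),
    bins = bins,
    genes = genes,
    cnv = cnv
  ), class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_names), "chromosomes,",
      nrow(x$bins), "bins of", x$bin_size, "bp,",
      if (is.null(x$genes)) 0L else nrow(x$genes), "genes\n")
  if (!is.null(x$cnv) && nrow(x$cnv) > 0)
    cat("  CNV segments:", nrow(x$cnv), "\n")
  invisible(x)
}

#' Ground-truth RT value per gene
#'
#' Looks up, for each gene, the timing of the genome bin containing the
#' gene's midpoint.
#'
#' @param genome A `genome_model`.
#' @return Named numeric vector of timing values in [0, 1], one per gene.
#' @export
gene_truth_rt <- function(genome) {
  assert_that(inherits(genome, "genome_model"), "need a genome_model")
  g <- genome$genes
  mid <- floor((g$start + g$end) / 2)
  bin_idx <- match(g$chrom, genome$chrom_names)
  offset <- (bin_idx - 1L) * (nrow(genome$bins) / length(genome$chrom_names))
  idx <- offset + floor(mid / genome$bin_size) + 1L
  stats::setNames(genome$bins$timing[idx], g$gene_id)
}
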