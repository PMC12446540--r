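#' Sliding-window specification
#'
#' Windows of `window_size` bp placed every `step` bp (defaults 200 kb / 40
#' kb, the standard RT profiling grid). `window_size` must be a multiple of
#' `step` so that sliding windows are exact sums of adjacent base bins.
#'
#' @param window_size Window width in bp.
#' @param step Interval between window starts in bp.
#' @return An object of class `window_spec`.
#' @export
#' @examples
#' window_spec()               # 200 kb windows every 40 kb
#' window_spec(2e5, 2e5)       # non-overlapping 200 kb bins
window_spec <- function(window_size = 200000L, step = 40000L) {
  assert_that(is_count(window_size) && is_count(step),
              "window_size and step must be positive integers")
  assert_that(step <= window_size, "step must be <= window_size")
  assert_that(window_size %% step == 0,
              "window_size must be divisible by step")
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step)),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat("window_spec:", x$window_size, "bp windows every", x$step, "bp\n")
  invisible(x)
}

#' Window grid for a genome extent
#'
#' One window starts at every multiple of `step` from 0 up to the chromosome
#' end; windows cover `[start, start + window_size)` clipped at the
#' chromosome end. Rows are sorted by (chrom, start).
#'
#' @param genome_extent Named numeric vector of chromosome sizes in bp.
#' @param spec A [window_spec()].
#' @return data.frame with chrom, start, end.
#' @export
make_windows <- function(genome_extent, spec = window_spec()) {
  assert_that(inherits(spec, "window_spec"), "spec must be a window_spec")
  assert_that(!is.null(names(genome_extent)) && all(genome_extent > 0),
              "genome_extent must be a named vector of positive sizes")
  out <- lapply(names(genome_extent), function(cn) {
    size <- genome_extent[[cn]]
    starts <- seq.int(0L, size - 1L, by = spec$step)
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + spec$window_size, size),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Count reads in sliding windows
#'
#' Counts each read position into every window containing it. Implemented
#' exactly as base-step binning (bins of `step` bp) followed by rolling sums
#' of `window_size / step` adjacent base bins, which is O(bins) rather than
#' O(reads x windows).
#'
#' @param reads Either a named list (one entry per cell) of data.frames with
#'   `chrom` and `pos` columns (0-based read positions), or a base-bin count
#'   matrix (rows = step-sized bins in `make_windows(genome_extent,
#'   window_spec(step, step))` order, columns = cells).
#' @param genome_extent Named vector of chromosome sizes in bp.
#' @param spec A [window_spec()].
#' @return A `window_count_matrix`: list with `windows` (data.frame), integer
#'   `counts` (windows x cells) and `spec`.
#' @export
#' @examples
#' reads <- list(c1 = data.frame(chrom = "chr1", pos = 100000))
#' wcm <- count_windows(reads, c(chr1 = 1e6), window_spec(200000, 40000))
#' sum(wcm$counts)   # the read falls in 3 overlapping windows
count_windows <- function(reads, genome_extent, spec = window_spec()) {
  assert_that(inherits(spec, "window_spec"), "spec must be a window_spec")
  base_spec <- window_spec(spec$step, spec$step)
  base_bins <- make_windows(genome_extent, base_spec)

  if (is.matrix(reads)) {
    assert_that(nrow(reads) == nrow(base_bins),
                "pre-binned matrix must have one row per ", spec$step,
                "-bp base bin (", nrow(base_bins), " expected)")
    assert_that(all(reads >= 0), "negative counts not allowed")
    base_counts <- reads
  } else {
    assert_that(is.list(reads) && !is.null(names(reads)),
                "reads must be a named list of per-cell data.frames")
    base_counts <- matrix(0L, nrow(base_bins), length(reads),
                          dimnames = list(NULL, names(reads)))
    n_per_chrom <- table(factor(base_bins$chrom, levels = names(genome_extent)))
    offsets <- stats::setNames(cumsum(c(0L, head(as.integer(n_per_chrom), -1L))),
                               names(genome_extent))
    for (i in seq_along(reads)) {
      df <- reads[[i]]
      if (nrow(df) == 0) next
      assert_that(all(c("chrom", "pos") %in% names(df)),
                  "per-cell read table needs chrom and pos columns")
      bad <- !(df$chrom %in% names(genome_extent)) |
        df$pos < 0 | df$pos >= genome_extent[df$chrom]
      if (any(bad)) {
        k <- which(bad)[1]
        stop2("read position outside declared extent: cell ", names(reads)[i],
              " ", df$chrom[k], ":", df$pos[k],
              class = "screpli_invalid_input")
      }
      idx <- offsets[df$chrom] + floor(df$pos / spec$step) + 1L
      tab <- tabulate(idx, nbins = nrow(base_bins))
      base_counts[, i] <- base_counts[, i] + tab
    }
  }

  ratio <- spec$window_size %/% spec$step
  windows <- make_windows(genome_extent, spec)
  if (ratio == 1L) {
    counts <- base_counts
  } else {
    # rolling sum of `ratio` adjacent base bins within each chromosome;
    # trailing windows clipped at the chromosome end sum fewer bins
    counts <- matrix(0L, nrow(windows), ncol(base_counts),
                     dimnames = list(NULL, colnames(base_counts)))
    for (cn in names(genome_extent)) {
      bi <- which(base_bins$chrom == cn)
      wi <- which(windows$chrom == cn)
      cs <- apply(base_counts[bi, , drop = FALSE], 2,
                  function(v) cumsum(as.numeric(v)))
      cs <- rbind(0, cs)
      n <- length(bi)
      hi <- pmin(seq_len(n) + ratio - 1L, n)
      counts[wi, ] <- cs[hi + 1L, , drop = FALSE] - cs[seq_len(n), , drop = FALSE]
    }
  }
  storage.mode(counts) <- "integer"
  structure(list(windows = windows, counts = counts, spec = spec),
            class = "window_count_matrix")
}

#' @export
print.window_count_matrix <- function(x, ...) {
  cat("window_count_matrix:", nrow(x$windows), "windows x",
      ncol(x$counts), "cells (", x$spec$window_size, "/", x$spec$step,
      "bp )\n")
  invisible(x)
}

#' Window count matrix directly from a binned-genome experiment
#'
#' Convenience adapter: treats the per-bin count matrix of a
#' [simulate_experiment()] fixture (bins of `genome$bin_size`) as a
#' non-overlapping window count matrix.
#'
#' @param genome A `genome_model`.
#' @param counts bins x cells integer matrix.
#' @return A `window_count_matrix` with step = window = bin size.
#' @export
wcm_from_bins <- function(genome, counts) {
  assert_that(inherits(genome, "genome_model"), "need a genome_model")
  assert_that(nrow(counts) == nrow(genome$bins),
              "counts rows must match genome bins")
  spec <- window_spec(genome$bin_size, genome$bin_size)
  windows <- genome$bins[, c("chrom", "start", "end")]
  rownames(windows) <- NULL
  structure(list(windows = windows,
                 counts = as.matrix(counts), spec = spec),
            class = "window_count_matrix")
}
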