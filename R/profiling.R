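#' G1 baseline and copy-number track from G1 control cells
#'
#' G1 cells carry a uniform two-copy genome, so their coverage is the
#' per-window reference against which S-phase copy gain is measured. Each G1
#' cell is scaled to unit genome-wide mean, the baseline is the per-window
#' mean of the scaled cells, and the copy estimate is `2 * baseline /
#' median(baseline)`. Windows with baseline below `floor_frac *
#' median(baseline)` (near-empty or unmappable) are marked missing and stay
#' missing in every downstream profile.
#'
#' @param wcm A `window_count_matrix`.
#' @param g1_cells Character vector of G1 cell ids (columns of `wcm`).
#' @param floor_frac Missingness floor as a fraction of the median baseline.
#' @return List with `baseline` (per-window, NA where missing), `copy`
#'   (per-window copy estimate, NA where missing), `missing` (logical) and
#'   `method` tag.
#' @export
g1_baseline <- function(wcm, g1_cells, floor_frac = 0.05) {
  assert_that(inherits(wcm, "window_count_matrix"), "need a window_count_matrix")
  assert_that(length(g1_cells) >= 1, "need at least one G1 control cell",
              class = "screpli_config_error")
  assert_that(all(g1_cells %in% colnames(wcm$counts)),
              "unknown G1 cell id(s): ",
              paste(setdiff(g1_cells, colnames(wcm$counts)), collapse = ", "))
  g1 <- wcm$counts[, g1_cells, drop = FALSE]
  scaled <- sweep(g1, 2, colMeans(g1), "/")
  baseline <- rowMeans(scaled)
  med <- stats::median(baseline[baseline > 0])
  missing <- !is.finite(baseline) | baseline < floor_frac * med
  baseline[missing] <- NA_real_
  copy <- 2 * baseline / med
  list(baseline = baseline, copy = copy, missing = missing,
       method = "scaled-G1-mean")
}

#' Normalize one cell against the G1 baseline
#'
#' The cell is scaled to unit genome-wide mean over non-missing windows and
#' divided per window by the baseline. Because the baseline is proportional
#' to constitutive copy number, the division cancels CNV: a copy-3 segment
#' inflates cell and baseline alike, leaving the ratio driven purely by
#' replication state. An all-zero cell yields a degenerate (all-NA) result
#' flagged via the `"degenerate"` attribute rather than an error.
#'
#' @param cell_counts Integer vector of per-window counts for one cell.
#' @param baseline Per-window baseline from [g1_baseline()].
#' @param copy Optional copy track (kept for interface symmetry; the
#'   baseline division already adjusts CNV per window).
#' @return Numeric vector of per-window ratios (NA where missing).
#' @export
normalize_cell <- function(cell_counts, baseline, copy = NULL) {
  assert_that(length(cell_counts) == length(baseline),
              "cell_counts and baseline lengths differ")
  ok <- !is.na(baseline)
  total <- mean(cell_counts[ok])
  if (!is.finite(total) || total <= 0) {
    out <- rep(NA_real_, length(baseline))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ratio <- rep(NA_real_, length(baseline))
  ratio[ok] <- (cell_counts[ok] / total) / baseline[ok]
  attr(ratio, "degenerate") <- FALSE
  ratio
}

# Deterministic 1-D two-means on a numeric vector: centers initialized at
# the 25th/75th percentiles, alternating assignment/update to convergence.
two_means_1d <- function(x, max_iter = 100L) {
  c1 <- stats::quantile(x, 0.25, names = FALSE)
  c2 <- stats::quantile(x, 0.75, names = FALSE)
  if (c1 == c2) c2 <- c1 + .Machine$double.eps
  assign_hi <- abs(x - c2) < abs(x - c1)
  for (i in seq_len(max_iter)) {
    m1 <- if (any(!assign_hi)) mean(x[!assign_hi]) else c1
    m2 <- if (any(assign_hi)) mean(x[assign_hi]) else c2
    new_hi <- abs(x - m2) < abs(x - m1)
    if (identical(new_hi, assign_hi)) break
    assign_hi <- new_hi
  }
  list(hi = assign_hi,
       centers = c(lo = if (any(!assign_hi)) mean(x[!assign_hi]) else NA_real_,
                   hi = if (any(assign_hi)) mean(x[assign_hi]) else NA_real_))
}

#' Binarize a normalized RT ratio into replication states
#'
#' Splits the per-window log2 ratios into two clusters with deterministic
#' 1-D two-means (centers initialized at the 25th/75th percentiles); the
#' higher-coverage cluster is the replicated state 1. If the cluster centers
#' are closer than `min_separation` log2 units the profile is not bimodal
#' (e.g. a G1 or G2 cell, where coverage is uniform) and every state is set
#' missing with the `"non_bimodal"` attribute set.
#'
#' @param ratio Per-window normalized ratio (NAs allowed).
#' @param min_separation Minimum cluster-center separation in log2 units.
#' @param min_windows Minimum number of non-missing windows required.
#' @return Integer vector of states (0, 1 or NA) with attribute
#'   `"non_bimodal"` (logical) and `"separation"` (log2 units).
#' @export
binarize <- function(ratio, min_separation = 0.15, min_windows = 20L) {
  ok <- which(is.finite(ratio) & ratio > 0)
  assert_that(length(ok) >= min_windows,
              "binarize needs >= ", min_windows, " non-missing windows, got ",
              length(ok), class = "screpli_degenerate_input")
  lr <- log2(ratio[ok])
  km <- two_means_1d(lr)
  sep <- unname(km$centers["hi"] - km$centers["lo"])
  states <- rep(NA_integer_, length(ratio))
  if (!is.finite(sep) || sep < min_separation) {
    attr(states, "non_bimodal") <- TRUE
    attr(states, "separation") <- sep
    return(states)
  }
  states[ok] <- as.integer(km$hi)
  attr(states, "non_bimodal") <- FALSE
  attr(states, "separation") <- sep
  states
}

#' Rep score: fraction of the assessable genome replicated
#'
#' Mean of the non-missing binary states; a Rep score of 0.6 means 60% of
#' the assessable genome has been replicated.
#'
#' @param states Integer vector of per-window states (0/1/NA), or an
#'   `scrt_profile`.
#' @return Fraction in [0, 1].
#' @export
rep_score <- function(states) {
  if (inherits(states, "scrt_profile")) states <- states$state
  ok <- !is.na(states)
  assert_that(any(ok), "rep_score undefined: all states missing",
              class = "screpli_undefined_result")
  mean(states[ok])
}

#' Single-cell RT profiles for a whole experiment
#'
#' Runs the full profiling chain: G1 baseline and copy track from the
#' G1-gated control cells, per-cell normalization, binarization, and Rep
#' scores, for every non-G1 cell (S and G2 gates). Cell-cycle phase is
#' taken from the metadata gates, never inferred from the data.
#'
#' @param wcm A `window_count_matrix` over all cells.
#' @param meta Metadata data.frame with `cell_id` and `gate` columns.
#' @param min_separation,min_windows Passed to [binarize()].
#' @param floor_frac Passed to [g1_baseline()].
#' @param cells Cells to profile; default all S-phase cells (gates S1-S5).
#' @return An `scrt_profiles` object: list with `windows`, `ratio` (windows
#'   x cells), `state` (windows x cells), `rep_scores`, `flags` (per-cell
#'   character: "ok", "non-bimodal", "degenerate"), `baseline`, `copy`,
#'   `meta`.
#' @export
#' @examples
#' exp <- simulate_experiment(sim_config(seed = 1,
#'   n_cells_per_gate = c(G1 = 4, S3 = 2)), n_chrom = 1,
#'   bins_per_chrom = 300, n_genes = 0)
#' prof <- scrt_profiles(wcm_from_bins(exp$genome, exp$counts), exp$meta)
#' prof$rep_scores
scrt_profiles <- function(wcm, meta, min_separation = 0.15,
                          min_windows = 20L, floor_frac = 0.05,
                          cells = NULL) {
  assert_that(inherits(wcm, "window_count_matrix"), "need a window_count_matrix")
  meta <- validate_meta(meta, colnames(wcm$counts))
  g1_cells <- meta$cell_id[meta$gate == "G1"]
  bl <- g1_baseline(wcm, g1_cells, floor_frac = floor_frac)
  if (is.null(cells)) {
    cells <- meta$cell_id[meta$gate %in% c("S1", "S2", "S3", "S4", "S5")]
  }
  assert_that(all(cells %in% colnames(wcm$counts)), "unknown cell id in cells")

  n_w <- nrow(wcm$windows)
  ratio <- matrix(NA_real_, n_w, length(cells), dimnames = list(NULL, cells))
  state <- matrix(NA_integer_, n_w, length(cells), dimnames = list(NULL, cells))
  flags <- stats::setNames(rep("ok", length(cells)), cells)
  scores <- stats::setNames(rep(NA_real_, length(cells)), cells)
  for (cid in cells) {
    r <- normalize_cell(wcm$counts[, cid], bl$baseline, bl$copy)
    ratio[, cid] <- r
    if (isTRUE(attr(r, "degenerate"))) {
      flags[cid] <- "degenerate"
      next
    }
    s <- binarize(r, min_separation = min_separation,
                  min_windows = min_windows)
    state[, cid] <- s
    if (isTRUE(attr(s, "non_bimodal"))) {
      flags[cid] <- "non-bimodal"
    } else {
      scores[cid] <- rep_score(s)
    }
  }
  structure(list(windows = wcm$windows, ratio = ratio, state = state,
                 rep_scores = scores, flags = flags,
                 baseline = bl$baseline, copy = bl$copy, meta = meta),
            class = "scrt_profiles")
}

#' @export
print.scrt_profiles <- function(x, ...) {
  cat("scrt_profiles:", ncol(x$ratio), "cells x", nrow(x$windows),
      "windows;", sum(x$flags == "ok"), "ok,",
      sum(x$flags != "ok"), "flagged\n")
  invisible(x)
}

#' Export RT profiles as bedGraph tracks and a state matrix
#'
#' Writes one ratio bedGraph and one state bedGraph per cell (non-missing
#' windows only, sorted, 0-based half-open) plus combined ratio/state TSV
#' matrices that round-trip losslessly through [read_matrix_tsv()].
#'
#' @param profiles An `scrt_profiles`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
export_profiles <- function(profiles, out_dir) {
  assert_that(inherits(profiles, "scrt_profiles"), "need scrt_profiles")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(out_dir), "cannot create directory ", out_dir,
              class = "screpli_io_error")
  files <- character(0)
  w <- profiles$windows
  for (cid in colnames(profiles$ratio)) {
    for (what in c("ratio", "state")) {
      v <- profiles[[what]][, cid]
      ok <- !is.na(v)
      f <- file.path(out_dir, sprintf("%s_%s.bedGraph", cid, what))
      write_bedgraph(data.frame(chrom = w$chrom[ok], start = w$start[ok],
                                end = w$end[ok], value = v[ok]), f)
      files <- c(files, f)
    }
  }
  fr <- file.path(out_dir, "ratio_matrix.tsv")
  fs <- file.path(out_dir, "state_matrix.tsv")
  ids <- sprintf("%s:%d-%d", w$chrom, w$start, w$end)
  write_matrix_tsv(`rownames<-`(profiles$ratio, ids), fr, feature_col = "window")
  write_matrix_tsv(`rownames<-`(profiles$state, ids), fs, feature_col = "window")
  invisible(c(files, fr, fs))
}
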