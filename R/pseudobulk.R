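#' Select mid-S-phase cells
#'
#' Mid-S cells — sorting gates S2, S3 and S4 by default — are the cells with
#' roughly half the genome replicated, where early and late domains separate
#' most cleanly; they are the input to pseudo-bulk RT construction.
#'
#' @param meta Metadata data.frame with `cell_id` and `gate` columns.
#' @param gates Gates considered mid-S.
#' @return Character vector of cell ids, input order preserved.
#' @export
#' @examples
#' meta <- data.frame(cell_id = c("a", "b", "c"),
#'                    gate = c("S2", "G1", "S4"))
#' select_mid_s(meta)
select_mid_s <- function(meta, gates = c("S2", "S3", "S4")) {
  meta <- validate_meta(meta)
  assert_that(all(gates %in% gate_labels()), "unknown gate in gates",
              class = "screpli_invalid_input")
  meta$cell_id[meta$gate %in% gates]
}

#' Pseudo-bulk RT as the per-window fraction of replicated cells
#'
#' For each window, the pseudo-bulk RT value is the fraction of informative
#' (non-missing) mid-S cells already replicated there — a direct estimate of
#' replication timing on a 0-1 scale where higher = earlier. Windows
#' informed by fewer than `min_cells` cells are set missing.
#'
#' @param profiles An `scrt_profiles` (or a windows x cells 0/1/NA state
#'   matrix together with `windows`).
#' @param cells Cell ids to aggregate (default: every profiled cell).
#' @param min_cells Minimum informative cells per window.
#' @param windows Window data.frame when `profiles` is a bare matrix.
#' @return A `pseudobulk_rt`: list with `windows`, `rt` (per-window in
#'   [0, 1] or NA), `n_cells`, `method = "fraction"`.
#' @export
pseudobulk_fraction <- function(profiles, cells = NULL, min_cells = 3L,
                                windows = NULL) {
  if (inherits(profiles, "scrt_profiles")) {
    windows <- profiles$windows
    state <- profiles$state
  } else {
    assert_that(!is.null(windows), "windows required with a bare state matrix")
    state <- profiles
  }
  if (!is.null(cells)) {
    assert_that(all(cells %in% colnames(state)), "unknown cell id in cells")
    state <- state[, cells, drop = FALSE]
  }
  usable <- colSums(!is.na(state)) > 0
  assert_that(any(usable), "no usable profiles (all states missing)",
              class = "screpli_config_error")
  state <- state[, usable, drop = FALSE]
  n_inform <- rowSums(!is.na(state))
  rt <- rowMeans(state, na.rm = TRUE)
  rt[n_inform < min_cells] <- NA_real_
  structure(list(windows = windows, rt = rt, n_cells = ncol(state),
                 method = "fraction"),
            class = "pseudobulk_rt")
}

#' Pseudo-bulk RT by pooling mid-S reads into one entry
#'
#' Sums the raw window counts of the mid-S cells into a single pooled
#' column, normalizes it against the G1 baseline exactly like a single cell,
#' and rescales the ratio to [0, 1] by min-max over non-missing windows
#' after winsorizing at the 1st/99th percentiles (so a handful of extreme
#' windows cannot compress the scale).
#'
#' @param wcm A `window_count_matrix` over all cells.
#' @param mid_s_cells Cell ids to pool.
#' @param baseline,copy From [g1_baseline()].
#' @return A `pseudobulk_rt` with `method = "pooled"`.
#' @export
pseudobulk_pooled <- function(wcm, mid_s_cells, baseline, copy = NULL) {
  assert_that(inherits(wcm, "window_count_matrix"), "need a window_count_matrix")
  assert_that(length(mid_s_cells) >= 1, "need at least one mid-S cell",
              class = "screpli_config_error")
  assert_that(all(mid_s_cells %in% colnames(wcm$counts)),
              "mid-S cells absent from counts")
  pooled <- rowSums(wcm$counts[, mid_s_cells, drop = FALSE])
  ratio <- normalize_cell(pooled, baseline, copy)
  ok <- !is.na(ratio)
  lo <- stats::quantile(ratio[ok], 0.01, names = FALSE)
  hi <- stats::quantile(ratio[ok], 0.99, names = FALSE)
  r <- pmin(pmax(ratio, lo), hi)
  rt <- rep(NA_real_, length(ratio))
  if (hi > lo) {
    rt[ok] <- (r[ok] - lo) / (hi - lo)
  } else {
    rt[ok] <- 0
  }
  structure(list(windows = wcm$windows, rt = rt,
                 n_cells = length(mid_s_cells), method = "pooled",
                 ratio_raw = ratio),
            class = "pseudobulk_rt")
}

#' @export
print.pseudobulk_rt <- function(x, ...) {
  cat("pseudobulk_rt (", x$method, "): ", sum(!is.na(x$rt)), "/",
      length(x$rt), " windows, ", x$n_cells, " cells\n", sep = "")
  invisible(x)
}

#' Rank correlation of a pseudo-bulk profile with a reference RT track
#'
#' Each pseudo-bulk window is matched to the reference interval containing
#' its midpoint (midpoint containment — deterministic and resolution
#' agnostic); unmatched or missing windows are dropped and Spearman's rho is
#' computed over the matched pairs. Rank correlation makes the comparison
#' invariant to the two tracks' scales (the reference may be log2
#' early/late). A rho below -0.2 triggers a polarity warning rather than a
#' silent flip.
#'
#' @param pb A `pseudobulk_rt`.
#' @param ref Reference track data.frame: chrom, start, end, value
#'   (non-overlapping intervals within a chromosome).
#' @param min_matches Minimum matched windows (default 10).
#' @return List with `rho`, `n` (matched windows) and `method`.
#' @export
correlate_to_reference <- function(pb, ref, min_matches = 10L) {
  assert_that(inherits(pb, "pseudobulk_rt"), "need a pseudobulk_rt")
  assert_that(all(c("chrom", "start", "end", "value") %in% names(ref)),
              "ref needs chrom, start, end, value columns")
  w <- pb$windows
  mid <- floor((w$start + w$end) / 2)
  ref_val <- rep(NA_real_, nrow(w))
  for (cn in unique(w$chrom)) {
    ri <- ref[ref$chrom == cn, , drop = FALSE]
    if (nrow(ri) == 0) next
    ri <- ri[order(ri$start), , drop = FALSE]
    wi <- which(w$chrom == cn)
    idx <- findInterval(mid[wi], ri$start)
    hit <- idx >= 1 & idx <= nrow(ri)
    hit[hit] <- mid[wi][hit] < ri$end[idx[hit]]
    ref_val[wi[hit]] <- ri$value[idx[hit]]
  }
  ok <- !is.na(pb$rt) & !is.na(ref_val)
  assert_that(sum(ok) >= min_matches,
              "insufficient overlap: only ", sum(ok), " matched windows",
              class = "screpli_insufficient_overlap")
  rho <- stats::cor(pb$rt[ok], ref_val[ok], method = "spearman")
  if (is.finite(rho) && rho < -0.2) {
    warning("pseudo-bulk vs reference correlation is strongly negative (",
            round(rho, 3), "); check early/late polarity of the tracks")
  }
  list(rho = rho, n = sum(ok), method = "spearman")
}
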