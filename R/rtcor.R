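#' Assign an RT value to each gene
#'
#' A gene inherits the RT value of the window whose span contains the gene's
#' midpoint; among overlapping sliding windows, the one with the smallest
#' start is used. Genes whose window value is missing, or that fall outside
#' the window grid, are excluded (and counted in the `"n_dropped"`
#' attribute).
#'
#' @param rt Per-window RT values (numeric, NA = missing).
#' @param genes data.frame with gene_id, chrom, start, end.
#' @param windows Window data.frame (chrom, start, end) sorted by
#'   (chrom, start), as produced by [make_windows()].
#' @return data.frame (gene_id, rt_value) with attribute `"n_dropped"`.
#' @export
assign_gene_rt <- function(rt, genes, windows) {
  assert_that(length(rt) == nrow(windows),
              "rt length must equal number of windows")
  assert_that(all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
              "genes needs gene_id, chrom, start, end columns")
  mid <- floor((genes$start + genes$end) / 2)
  val <- rep(NA_real_, nrow(genes))
  outside <- rep(FALSE, nrow(genes))
  for (cn in unique(genes$chrom)) {
    wi <- which(windows$chrom == cn)
    gi <- which(genes$chrom == cn)
    if (length(wi) == 0) { outside[gi] <- TRUE; next }
    ws <- windows$start[wi]
    we <- windows$end[wi]
    # smallest-start window containing the midpoint: first window whose
    # start exceeds mid - window_size, checked for actual containment
    idx <- findInterval(mid[gi] - (we[1] - ws[1]), ws) + 1L
    idx <- pmax(idx, 1L)
    in_grid <- idx <= length(wi)
    contained <- in_grid & ws[pmin(idx, length(wi))] <= mid[gi] &
      mid[gi] < we[pmin(idx, length(wi))]
    outside[gi[!contained]] <- TRUE
    val[gi[contained]] <- rt[wi[idx[contained]]]
  }
  if (any(outside)) {
    warning(sum(outside), " gene(s) outside the window grid, excluded")
  }
  keep <- !outside & !is.na(val)
  out <- data.frame(gene_id = genes$gene_id[keep], rt_value = val[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Filter to genes expressed in at least one cell
#'
#' Keeps genes with log2 FPKM strictly greater than 1 in at least one cell;
#' gene order is preserved.
#'
#' @param m An `expr_matrix` with unit FPKM or log2FPKM.
#' @param threshold_log2 Expressed threshold on the log2 scale (default 1).
#' @return Character vector of gene ids.
#' @export
filter_expressed_genes <- function(m, threshold_log2 = 1) {
  calls <- expressed_call(m, threshold_log2)
  rownames(calls)[rowSums(calls, na.rm = TRUE) > 0]
}

#' Bin genes by RT and compute per-group expression probability
#'
#' Genes are sorted ascending by RT (ties broken by gene id so group
#' composition is reproducible), cut into consecutive non-overlapping groups
#' of exactly `group_size` genes (trailing partial group dropped), and each
#' group is summarized by its mean RT and its expression probability — the
#' mean of the per-gene expressed values, which may be binary calls (0/1)
#' or per-gene expression fractions in [0, 1].
#'
#' @param gene_rt data.frame (gene_id, rt_value) from [assign_gene_rt()].
#' @param expressed Named numeric vector in [0, 1] (typically binary), one
#'   value per gene; matched to `gene_rt$gene_id` by name.
#' @param group_size Genes per group (default 50).
#' @return An `rtrna_groups` data.frame (group_index, mean_rt, p_expressed,
#'   n_genes) with attributes `"n_genes_used"` and `"n_dropped"`.
#' @export
#' @examples
#' rt <- data.frame(gene_id = sprintf("g%03d", 1:100), rt_value = (1:100) / 100)
#' expressed <- setNames(rep(c(0, 1), each = 50), rt$gene_id)
#' binned_probability(rt, expressed, group_size = 50)
binned_probability <- function(gene_rt, expressed, group_size = 50L) {
  assert_that(is_count(group_size), "group_size must be a positive integer")
  assert_that(!is.null(names(expressed)), "expressed must be named by gene_id")
  common <- intersect(gene_rt$gene_id, names(expressed))
  gene_rt <- gene_rt[gene_rt$gene_id %in% common, , drop = FALSE]
  e <- expressed[gene_rt$gene_id]
  assert_that(all(e >= 0 & e <= 1, na.rm = TRUE),
              "expressed values must lie in [0, 1]")
  n_groups <- nrow(gene_rt) %/% group_size
  assert_that(n_groups >= 2,
              "need at least 2 full groups of ", group_size, " genes, have ",
              nrow(gene_rt), " genes", class = "screpli_insufficient_genes")
  ord <- order(gene_rt$rt_value, gene_rt$gene_id)
  rt_sorted <- gene_rt$rt_value[ord]
  e_sorted <- e[ord]
  used <- n_groups * group_size
  grp <- rep(seq_len(n_groups), each = group_size)
  out <- data.frame(
    group_index = seq_len(n_groups),
    mean_rt = as.numeric(tapply(rt_sorted[seq_len(used)], grp, mean)),
    p_expressed = as.numeric(tapply(e_sorted[seq_len(used)], grp, mean)),
    n_genes = group_size
  )
  attr(out, "n_genes_used") <- used
  attr(out, "n_dropped") <- nrow(gene_rt) - used
  class(out) <- c("rtrna_groups", "data.frame")
  out
}

#' Fit the RT-expression slope over gene groups
#'
#' Ordinary least squares of per-group expression probability on per-group
#' mean RT. The slope is in units of probability per RT unit: a slope of
#' 0.6 means a gene at the earliest RT is 60 percentage points more likely
#' to be expressed than one at the latest.
#'
#' @param groups An `rtrna_groups` data.frame.
#' @return List with `slope`, `intercept`, `n_groups`; or, when the group
#'   RT values have no variance, `slope = NA` with a `reason`.
#' @export
fit_slope <- function(groups) {
  assert_that(all(c("mean_rt", "p_expressed") %in% names(groups)),
              "groups needs mean_rt and p_expressed")
  assert_that(nrow(groups) >= 2, "need >= 2 groups")
  if (stats::var(groups$mean_rt) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_,
                n_groups = nrow(groups), reason = "no RT variance"))
  }
  fit <- stats::lm(p_expressed ~ mean_rt, data = groups)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       n_groups = nrow(groups))
}

#' Per-cell RT-expression slope
#'
#' The per-cell analogue of the pseudo-bulk fit: the cell's binary
#' replication states provide a 0/1 RT value per gene, the cell's own
#' expressed calls provide the binary expression, and the same
#' sort-bin-fit procedure is applied. The slope then estimates
#' P(expressed | replicated) - P(expressed | unreplicated) for that cell.
#' The gene filter (expressed in at least one cell) is computed on the full
#' matrix and must be supplied via `gene_ids`.
#'
#' @param cell_states Per-window 0/1/NA replication states for the cell.
#' @param expr_cell Named FPKM vector for the cell (full gene set).
#' @param genes Gene annotation data.frame (gene_id, chrom, start, end).
#' @param windows Window data.frame matching `cell_states`.
#' @param gene_ids Genes passing the population-level expressed filter.
#' @param group_size Genes per group (default 50).
#' @param threshold_log2 Expressed threshold (default 1).
#' @return List with `slope`, `intercept`, `n_groups`, `n_genes`; `slope`
#'   is NA with a `reason` when the cell has no RT variance among retained
#'   genes (e.g. a fully unreplicated or fully replicated genome).
#' @export
per_cell_slope <- function(cell_states, expr_cell, genes, windows,
                           gene_ids, group_size = 50L, threshold_log2 = 1) {
  genes <- genes[genes$gene_id %in% gene_ids, , drop = FALSE]
  gene_rt <- assign_gene_rt(as.numeric(cell_states), genes, windows)
  if (nrow(gene_rt) < 2 * group_size) {
    return(list(slope = NA_real_, reason = "too few genes with defined RT"))
  }
  if (length(unique(gene_rt$rt_value)) < 2) {
    return(list(slope = NA_real_, reason = "no RT variance"))
  }
  expressed <- as.numeric(log2(expr_cell[gene_rt$gene_id]) > threshold_log2)
  names(expressed) <- gene_rt$gene_id
  groups <- binned_probability(gene_rt, expressed, group_size)
  fit <- fit_slope(groups)
  fit$n_genes <- attr(groups, "n_genes_used")
  fit
}

#' Per-cell slope table with population tests
#'
#' Computes the RT-expression slope for every profiled cell, attaches Rep
#' scores, and runs the population-level tests: a Wilcoxon signed-rank test
#' of the slope median against 0, and the Pearson correlation between slope
#' and Rep score.
#'
#' @param profiles An `scrt_profiles`.
#' @param expr An `expr_matrix` (unit FPKM) over the same cells.
#' @param genes Gene annotations (gene_id, chrom, start, end).
#' @param group_size Genes per group (default 50).
#' @param threshold_log2 Expressed threshold (default 1).
#' @return A `slope_table`: list with `cells` (data.frame cell_id, slope,
#'   rep_score, n_groups, reason), `signed_rank_p`, `pearson_r`.
#' @export
slope_table <- function(profiles, expr, genes, group_size = 50L,
                        threshold_log2 = 1) {
  assert_that(inherits(profiles, "scrt_profiles"), "need scrt_profiles")
  check_unit(expr, "FPKM", "slope_table")
  gene_ids <- filter_expressed_genes(expr, threshold_log2)
  cells <- colnames(profiles$state)
  assert_that(all(cells %in% colnames(expr$values)),
              "expression matrix missing profiled cells")
  rows <- lapply(cells, function(cid) {
    fit <- per_cell_slope(profiles$state[, cid], expr$values[, cid],
                          genes, profiles$windows, gene_ids,
                          group_size, threshold_log2)
    data.frame(cell_id = cid,
               slope = fit$slope,
               rep_score = unname(profiles$rep_scores[cid]),
               n_groups = fit$n_groups %||% NA_integer_,
               reason = fit$reason %||% "",
               stringsAsFactors = FALSE)
  })
  cells_df <- do.call(rbind, rows)
  ok <- !is.na(cells_df$slope)
  p <- if (sum(cells_df$slope[ok] != 0) >= 5) {
    slopes_signed_rank(cells_df$slope[ok])
  } else NA_real_
  r <- if (sum(ok & !is.na(cells_df$rep_score)) >= 3) {
    slope_vs_repscore(cells_df[ok, , drop = FALSE])
  } else NA_real_
  structure(list(cells = cells_df, signed_rank_p = p, pearson_r = r),
            class = "slope_table")
}

#' @export
print.slope_table <- function(x, ...) {
  ok <- !is.na(x$cells$slope)
  cat("slope_table:", sum(ok), "cells with defined slope (of",
      nrow(x$cells), ")\n")
  cat("  median slope:", round(stats::median(x$cells$slope[ok]), 4),
      " signed-rank p:", format(x$signed_rank_p, digits = 4),
      " Pearson r(slope, Rep score):", round(x$pearson_r, 3), "\n")
  invisible(x)
}

#' Wilcoxon signed-rank test of slopes against zero
#'
#' Two-sided test that the median slope differs from 0 (the no-association
#' condition). Zero slopes are dropped; the exact distribution is used for
#' n <= 25 without ties, the normal approximation with continuity
#' correction otherwise (the behavior of [stats::wilcox.test()]).
#'
#' @param slopes Numeric vector of per-cell slopes.
#' @return Two-sided p value.
#' @export
#' @examples
#' slopes_signed_rank(c(1, 2, 3, 4, 5, 6))  # 2/64 = 0.03125
slopes_signed_rank <- function(slopes) {
  slopes <- slopes[!is.na(slopes)]
  nonzero <- slopes[slopes != 0]
  assert_that(length(nonzero) >= 5,
              "signed-rank test needs >= 5 non-zero slopes, got ",
              length(nonzero), class = "screpli_insufficient_data")
  if (length(nonzero) == 0) {
    warning("all slopes zero; p = 1")
    return(1)
  }
  # with tied |slopes| the exact distribution is unavailable and
  # wilcox.test falls back to the normal approximation; suppress its note
  suppressWarnings(
    stats::wilcox.test(nonzero, mu = 0, alternative = "two.sided",
                       exact = length(nonzero) <= 25, correct = TRUE)$p.value)
}

#' Pearson correlation of slope against Rep score
#'
#' Asks whether the within-cell RT-expression association strengthens as
#' cells progress through S phase.
#'
#' @param table data.frame with `slope` and `rep_score` columns (or a
#'   `slope_table`).
#' @return Pearson r, or NA with attribute `"reason"` when either variable
#'   has zero variance.
#' @export
slope_vs_repscore <- function(table) {
  if (inherits(table, "slope_table")) table <- table$cells
  ok <- !is.na(table$slope) & !is.na(table$rep_score)
  assert_that(sum(ok) >= 3, "need >= 3 cells with slope and Rep score",
              class = "screpli_insufficient_data")
  x <- table$slope[ok]; y <- table$rep_score[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero variance"
    return(out)
  }
  stats::cor(x, y, method = "pearson")
}

#' Early vs late replicating gene expression test
#'
#' Splits genes at pseudo-bulk RT >= `threshold` (early) versus < threshold
#' (late) and compares per-gene mean log2 FPKM between the two groups with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param gene_rt data.frame (gene_id, rt_value) on the pseudo-bulk 0-1
#'   scale.
#' @param expr An `expr_matrix` (unit FPKM).
#' @param threshold Early/late boundary (default 0.5; a gene at exactly the
#'   boundary is early).
#' @return List with `median_early`, `median_late`, `n_early`, `n_late`,
#'   `statistic` (rank-sum W), `p`; or `p = NA` with `reason` when a group
#'   is empty.
#' @export
early_late_expression_test <- function(gene_rt, expr, threshold = 0.5) {
  check_unit(expr, "FPKM", "early_late_expression_test")
  common <- intersect(gene_rt$gene_id, rownames(expr$values))
  gene_rt <- gene_rt[gene_rt$gene_id %in% common, , drop = FALSE]
  mean_log2 <- rowMeans(log2(expr$values[gene_rt$gene_id, , drop = FALSE]))
  early <- gene_rt$rt_value >= threshold
  if (!any(early) || all(early)) {
    return(list(median_early = NA_real_, median_late = NA_real_,
                n_early = sum(early), n_late = sum(!early),
                statistic = NA_real_, p = NA_real_,
                reason = "empty early or late group"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(mean_log2[early], mean_log2[!early],
                       alternative = "two.sided"))
  list(median_early = stats::median(mean_log2[early]),
       median_late = stats::median(mean_log2[!early]),
       n_early = sum(early), n_late = sum(!early),
       statistic = unname(wt$statistic), p = wt$p.value)
}
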