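#' Expression matrix with an explicit unit tag
#'
#' A genes x cells matrix of nonnegative values carrying its unit
#' (`counts`, `FPKM`, `TPM`, `log2FPKM` or `scaled`) so that pipelines can
#' refuse to silently mix units. Unit transitions happen only through the
#' conversion operations ([to_fpkm()], [to_tpm()], [scale_genes()]), each of
#' which logs its transition.
#'
#' @param values Numeric matrix with gene rownames and cell colnames.
#' @param unit One of `"counts"`, `"FPKM"`, `"TPM"`, `"log2FPKM"`, `"scaled"`.
#' @param gene_lengths Optional named vector of gene lengths in bp
#'   (required later for counts -> FPKM/TPM).
#'
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, unit, gene_lengths = NULL) {
  units <- c("counts", "FPKM", "TPM", "log2FPKM", "scaled")
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  assert_that(unit %in% units, "unit must be one of ",
              paste(units, collapse = ", "), class = "screpli_unit_error")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "values must have gene rownames and cell colnames")
  assert_that(!anyDuplicated(rownames(values)),
              "duplicated gene ids in expression matrix")
  if (!unit %in% c("scaled", "log2FPKM")) {
    assert_that(all(values >= 0, na.rm = TRUE),
                "negative values not allowed for unit ", unit)
  }
  if (!is.null(gene_lengths)) {
    assert_that(all(rownames(values) %in% names(gene_lengths)),
                "gene_lengths missing for some genes")
    gene_lengths <- gene_lengths[rownames(values)]
    assert_that(all(gene_lengths > 0), "gene lengths must be positive")
  }
  structure(list(values = values, unit = unit, gene_lengths = gene_lengths),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "cells, unit:", x$unit, "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

check_unit <- function(m, allowed, op) {
  assert_that(inherits(m, "expr_matrix"), op, " needs an expr_matrix")
  assert_that(m$unit %in% allowed,
              op, " requires unit ", paste(allowed, collapse = " or "),
              ", got ", m$unit, class = "screpli_unit_error")
  invisible(TRUE)
}

#' Convert raw counts to FPKM
#'
#' FPKM_gc = count_gc / (length_g/1e3 * total_c/1e6): fragments per kilobase
#' of transcript per million mapped reads. Cells with zero total counts are
#' flagged and their column set to NA.
#'
#' @param m An `expr_matrix` with unit `"counts"` and gene lengths.
#' @return An `expr_matrix` with unit `"FPKM"`; attribute `"flagged_cells"`
#'   names zero-total cells.
#' @export
to_fpkm <- function(m) {
  check_unit(m, "counts", "to_fpkm")
  assert_that(!is.null(m$gene_lengths), "to_fpkm needs gene_lengths")
  totals <- colSums(m$values)
  bad <- totals <= 0
  totals[bad] <- NA_real_
  fpkm <- m$values / (m$gene_lengths / 1e3)
  fpkm <- sweep(fpkm, 2, totals / 1e6, "/")
  log_msg("expression", "unit transition counts -> FPKM (",
          sum(bad), " zero-total cells flagged)")
  out <- expression_matrix(fpkm, "FPKM", m$gene_lengths)
  attr(out, "flagged_cells") <- colnames(m$values)[bad]
  out
}

#' Convert raw counts to TPM
#'
#' TPM_gc = rate_gc / sum_g(rate_gc) * 1e6 with rate = count / length;
#' every non-degenerate column sums to one million.
#'
#' @param m An `expr_matrix` with unit `"counts"` and gene lengths.
#' @return An `expr_matrix` with unit `"TPM"`.
#' @export
to_tpm <- function(m) {
  check_unit(m, "counts", "to_tpm")
  assert_that(!is.null(m$gene_lengths), "to_tpm needs gene_lengths")
  rate <- m$values / m$gene_lengths
  denom <- colSums(rate)
  bad <- denom <= 0
  denom[bad] <- NA_real_
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  log_msg("expression", "unit transition counts -> TPM (",
          sum(bad), " zero-total cells flagged)")
  out <- expression_matrix(tpm, "TPM", m$gene_lengths)
  attr(out, "flagged_cells") <- colnames(m$values)[bad]
  out
}

#' Per-gene z-scaling across cells
#'
#' scaled value = (x - mu) / sigma per gene, where mu and sigma are the mean
#' and standard deviation (n - 1 denominator) of that gene across cells.
#' Zero-variance genes become all-zero rows and are flagged.
#'
#' @param m An `expr_matrix` with unit `"TPM"` or `"FPKM"`.
#' @return An `expr_matrix` with unit `"scaled"`; attribute
#'   `"zero_variance_genes"` lists flagged genes.
#' @export
scale_genes <- function(m) {
  check_unit(m, c("TPM", "FPKM"), "scale_genes")
  assert_that(ncol(m$values) >= 2, "scale_genes needs >= 2 cells",
              class = "screpli_invalid_argument")
  mu <- rowMeans(m$values)
  sdv <- apply(m$values, 1, stats::sd)
  zero_var <- sdv == 0 | !is.finite(sdv)
  sdv[zero_var] <- 1
  scaled <- (m$values - mu) / sdv
  scaled[zero_var, ] <- 0
  log_msg("expression", "unit transition ", m$unit, " -> scaled (",
          sum(zero_var), " zero-variance genes flagged)")
  out <- expression_matrix(scaled, "scaled", m$gene_lengths)
  attr(out, "zero_variance_genes") <- rownames(m$values)[zero_var]
  out
}

#' Binary expressed / not-expressed calls
#'
#' A gene is called expressed in a cell when log2 FPKM is strictly greater
#' than `threshold_log2` (default 1); the boundary log2 FPKM = 1 is "not
#' expressed". FPKM = 0 maps to -Inf on the log2 scale and is never
#' expressed (no pseudocount).
#'
#' @param m An `expr_matrix` with unit `"FPKM"` or `"log2FPKM"`.
#' @param threshold_log2 Threshold on the log2 FPKM scale.
#' @return Integer 0/1 matrix, genes x cells.
#' @export
expressed_call <- function(m, threshold_log2 = 1) {
  check_unit(m, c("FPKM", "log2FPKM"), "expressed_call")
  v <- m$values
  if (m$unit == "FPKM") {
    out <- (v > 2^threshold_log2)
  } else {
    out <- (v > threshold_log2)
  }
  mode(out) <- "integer"
  out
}

#' Compare phase-marker scores between cell-cycle phase groups
#'
#' Per cell, the marker score is the mean scaled expression over the marker
#' genes; phases are then compared pairwise with two-sided Welch (unequal
#' variance) t tests, flagged significant at p <= 0.05. Marker genes absent
#' from the matrix are dropped with a warning; phases with fewer than two
#' cells are reported as not compared rather than failing.
#'
#' @param scaled An `expr_matrix` with unit `"scaled"`.
#' @param markers Named list: phase label (G1, S, G2M) -> character vector
#'   of marker gene ids.
#' @param meta Cell metadata data.frame with `cell_id` and `gate` columns;
#'   gates map to phases as G1 -> G1, S1-S5 -> S, G2 -> G2M.
#' @param alpha Significance cutoff (default 0.05).
#' @return data.frame with marker_set, phase_a, phase_b, n_a, n_b, t, p,
#'   significant, compared.
#' @export
marker_phase_comparison <- function(scaled, markers, meta, alpha = 0.05) {
  check_unit(scaled, "scaled", "marker_phase_comparison")
  assert_that(is.list(markers) && length(markers) > 0 &&
                !is.null(names(markers)), "markers must be a named list")
  meta <- validate_meta(meta, colnames(scaled$values))
  phase <- c(G1 = "G1", S1 = "S", S2 = "S", S3 = "S", S4 = "S", S5 = "S",
             G2 = "G2M")[meta$gate]
  phases <- c("G1", "S", "G2M")

  rows <- list()
  for (ms in names(markers)) {
    ids <- markers[[ms]]
    present <- ids %in% rownames(scaled$values)
    if (!all(present)) {
      warning(sprintf("marker set %s: %d gene(s) absent from matrix, excluded",
                      ms, sum(!present)))
    }
    ids <- ids[present]
    assert_that(length(ids) > 0, "marker set ", ms, " has no resolvable genes")
    score <- colMeans(scaled$values[ids, meta$cell_id, drop = FALSE])
    for (i in 1:2) for (j in (i + 1):3) {
      a <- phases[i]; b <- phases[j]
      xa <- score[phase == a]; xb <- score[phase == b]
      if (length(xa) < 2 || length(xb) < 2) {
        rows[[length(rows) + 1L]] <- data.frame(
          marker_set = ms, phase_a = a, phase_b = b,
          n_a = length(xa), n_b = length(xb),
          t = NA_real_, p = NA_real_, significant = NA, compared = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      tt <- stats::t.test(xa, xb, var.equal = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        marker_set = ms, phase_a = a, phase_b = b,
        n_a = length(xa), n_b = length(xb),
        t = unname(tt$statistic), p = tt$p.value,
        significant = tt$p.value <= alpha, compared = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
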