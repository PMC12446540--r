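# Readers and writers for the plain-text exchange formats used throughout:
# BED-like interval tables, bedGraph tracks, feature x cell TSV matrices and
# cell metadata. All coordinates are 0-based half-open.

read_delim_checked <- function(path, what) {
  assert_that(file.exists(path), what, " file not found: ", path,
              class = "screpli_io_error")
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

validate_intervals <- function(df, path, require_sorted = FALSE) {
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$end <= df$start)
  if (length(bad) > 0) {
    k <- bad[1]
    stop2("malformed interval in ", path, " line ", k + 1L, ": ",
          paste(df$chrom[k], df$start[k], df$end[k]),
          class = "screpli_invalid_input")
  }
  invisible(df)
}

#' Read / write BED-like interval tables
#'
#' Tab-separated, 0-based half-open, first three columns chrom/start/end,
#' any extra numeric columns preserved. A header line is expected on read
#' (written by [write_bed()]).
#'
#' @param path File path.
#' @param df data.frame with chrom, start, end and optional extra columns.
#' @return `read_bed()`: data.frame sorted by (chrom, start).
#' @export
read_bed <- function(path) {
  df <- read_delim_checked(path, "BED")
  assert_that(all(c("chrom", "start", "end") %in% names(df)),
              "BED file ", path, " needs chrom, start, end columns",
              class = "screpli_invalid_input")
  validate_intervals(df, path)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_bed
#' @export
write_bed <- function(df, path) {
  assert_that(all(c("chrom", "start", "end") %in% names(df)),
              "need chrom, start, end columns")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write bedGraph tracks
#'
#' Four columns (chrom, start, end, value), no header, 0-based half-open,
#' sorted on write. With `check_overlap = TRUE` (required for reference RT
#' tracks) overlapping intervals within a chromosome are rejected with the
#' offending line reported.
#'
#' @param path File path.
#' @param df data.frame with chrom, start, end, value.
#' @param check_overlap Reject overlapping intervals within a chromosome.
#' @return `read_bedgraph()`: data.frame sorted by (chrom, start).
#' @export
read_bedgraph <- function(path, check_overlap = FALSE) {
  assert_that(file.exists(path), "bedGraph file not found: ", path,
              class = "screpli_io_error")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE, comment.char = "#")
  validate_intervals(df, path)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (check_overlap) {
    for (cn in unique(df$chrom)) {
      sub <- df[df$chrom == cn, , drop = FALSE]
      ov <- which(sub$start[-1] < sub$end[-nrow(sub)])
      if (length(ov) > 0) {
        stop2("overlapping intervals in ", path, " on ", cn, " near ",
              sub$start[ov[1] + 1L], class = "screpli_invalid_input")
      }
    }
  }
  df
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(df, path) {
  assert_that(all(c("chrom", "start", "end", "value") %in% names(df)),
              "need chrom, start, end, value columns")
  df <- df[order(df$chrom, df$start), c("chrom", "start", "end", "value")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write feature x cell TSV matrices
#'
#' First column is the feature id, one column per cell. An optional
#' `#unit: <unit>` header line carries the expression unit; when present on
#' read the result is returned as an [expression_matrix()].
#'
#' @param path File path.
#' @param m Numeric matrix with rownames (features) and colnames (cells),
#'   or an `expr_matrix` (its unit is written as a `#unit:` header).
#' @param feature_col Name for the feature id column on write.
#' @return `read_matrix_tsv()`: a numeric matrix, or an `expr_matrix` when
#'   the file carries a `#unit:` header.
#' @export
read_matrix_tsv <- function(path) {
  assert_that(file.exists(path), "matrix file not found: ", path,
              class = "screpli_io_error")
  first <- readLines(path, n = 1L)
  unit <- NULL
  if (startsWith(first, "#unit:")) {
    unit <- trimws(sub("^#unit:", "", first))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  dup <- df[[1]][duplicated(df[[1]])]
  if (length(dup) > 0) {
    stop2("duplicated feature id in ", path, ": ", dup[1],
          class = "screpli_invalid_input")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!is.null(unit)) expression_matrix(m, unit) else m
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(m, path, feature_col = "feature") {
  unit <- NULL
  if (inherits(m, "expr_matrix")) {
    unit <- m$unit
    m <- m$values
  }
  assert_that(!is.null(rownames(m)) && !is.null(colnames(m)),
              "matrix needs rownames and colnames")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(unit)) writeLines(paste0("#unit: ", unit), con)
  writeLines(paste(c(feature_col, colnames(m)), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read and validate cell metadata
#'
#' Metadata is a TSV with at least `cell_id` and `gate` columns; gates must
#' be among the seven sorting-gate labels and cell ids unique.
#'
#' @param path TSV path.
#' @return data.frame with cell_id and gate (plus any extra columns).
#' @export
read_meta <- function(path) {
  df <- read_delim_checked(path, "metadata")
  validate_meta(df)
}

#' Validate a metadata data.frame
#'
#' @param meta data.frame with cell_id and gate columns.
#' @param expected_cells Optional cell ids that must all be present.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_meta <- function(meta, expected_cells = NULL) {
  assert_that(is.data.frame(meta) &&
                all(c("cell_id", "gate") %in% names(meta)),
              "metadata needs cell_id and gate columns",
              class = "screpli_invalid_input")
  bad <- setdiff(unique(meta$gate), gate_labels())
  assert_that(length(bad) == 0, "unknown gate label(s): ",
              paste(bad, collapse = ", "), class = "screpli_invalid_input")
  assert_that(!anyDuplicated(meta$cell_id), "duplicated cell_id in metadata",
              class = "screpli_invalid_input")
  if (!is.null(expected_cells)) {
    missing <- setdiff(meta$cell_id, expected_cells)
    assert_that(length(missing) == 0,
                "metadata cells absent from matrix: ",
                paste(utils::head(missing, 3), collapse = ", "),
                class = "screpli_invalid_input")
  }
  meta
}
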