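#' Write a simulated experiment to disk as a plain-text fixture
#'
#' Emits the complete study as diff-able text: bins BED (with timing and
#' copy columns), per-cell count TSV, expression TSV (with `#unit:` header),
#' metadata TSV, truth state TSV, and a JSON manifest recording the seed and
#' config, so the whole fixture is reproducible from the manifest alone.
#' Round-trips losslessly through [read_fixture()].
#'
#' @param experiment A [simulate_experiment()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named vector of the files written.
#' @export
write_fixture <- function(experiment, out_dir) {
  assert_that(is.list(experiment) && !is.null(experiment$genome),
              "experiment must come from simulate_experiment()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(out_dir), "cannot create directory ", out_dir,
              class = "screpli_io_error")
  g <- experiment$genome
  files <- c(
    bins = file.path(out_dir, "bins.bed"),
    genes = file.path(out_dir, "genes.bed"),
    counts = file.path(out_dir, "counts.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    meta = file.path(out_dir, "meta.tsv"),
    truth = file.path(out_dir, "truth_states.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_bed(g$bins, files["bins"])
  if (!is.null(g$genes)) write_bed(g$genes, files["genes"])
  bin_ids <- sprintf("%s:%d-%d", g$bins$chrom, g$bins$start, g$bins$end)
  write_matrix_tsv(`rownames<-`(experiment$counts, bin_ids), files["counts"],
                   feature_col = "bin")
  if (!is.null(experiment$expression)) {
    write_matrix_tsv(experiment$expression, files["expression"],
                     feature_col = "gene_id")
  } else {
    files <- files[names(files) != "expression"]
  }
  utils::write.table(experiment$meta, files["meta"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(`rownames<-`(experiment$states_true, bin_ids),
                   files["truth"], feature_col = "bin")
  cfg <- experiment$config
  manifest <- list(
    seed = cfg$seed,
    config = unclass(cfg),
    n_chrom = length(g$chrom_names),
    bin_size = g$bin_size,
    n_bins = nrow(g$bins),
    n_genes = if (is.null(g$genes)) 0L else nrow(g$genes),
    n_cells = ncol(experiment$counts)
  )
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(files)
}

#' Read a fixture directory back into memory
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `bins`, `genes`, `counts`, `expression`
#'   (an `expr_matrix`), `meta`, `states_true`, `manifest`.
#' @export
read_fixture <- function(dir) {
  assert_that(dir.exists(dir), "fixture directory not found: ", dir,
              class = "screpli_io_error")
  genes_path <- file.path(dir, "genes.bed")
  expr_path <- file.path(dir, "expression.tsv")
  list(
    bins = read_bed(file.path(dir, "bins.bed")),
    genes = if (file.exists(genes_path)) read_bed(genes_path) else NULL,
    counts = read_matrix_tsv(file.path(dir, "counts.tsv")),
    expression = if (file.exists(expr_path)) read_matrix_tsv(expr_path) else NULL,
    meta = read_meta(file.path(dir, "meta.tsv")),
    states_true = read_matrix_tsv(file.path(dir, "truth_states.tsv")),
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                   simplifyVector = TRUE)
  )
}
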