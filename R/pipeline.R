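#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable of the analysis in one validated object that
#' round-trips losslessly through JSON; every pipeline report embeds the
#' resolved config.
#'
#' @param seed Integer seed for the synthetic stage.
#' @param sim A [sim_config()] for the synthetic stage (its seed is
#'   overridden by `seed`).
#' @param mid_s_gates Gates pooled into the pseudo-bulk (default S2-S4).
#' @param group_size Genes per RT group (default 50).
#' @param expressed_log2 Expressed-call threshold on log2 FPKM (default 1).
#' @param early_late Early/late RT boundary (default 0.5, boundary = early).
#' @param min_separation Binarization cluster-separation floor, log2 units.
#' @param n_chrom,bins_per_chrom,bin_size,n_genes Synthetic genome shape.
#' @param out_dir Optional directory for artifacts (NULL = in-memory only).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       sim = sim_config(seed = seed),
                       mid_s_gates = c("S2", "S3", "S4"),
                       group_size = 50L,
                       expressed_log2 = 1,
                       early_late = 0.5,
                       min_separation = 0.15,
                       n_chrom = 2L,
                       bins_per_chrom = 500L,
                       bin_size = 200000L,
                       n_genes = 4000L,
                       out_dir = NULL) {
  sim$seed <- as.integer(seed)
  assert_that(all(mid_s_gates %in% gate_labels()), "unknown mid-S gate")
  structure(list(seed = as.integer(seed), sim = sim,
                 mid_s_gates = mid_s_gates,
                 group_size = as.integer(group_size),
                 expressed_log2 = expressed_log2,
                 early_late = early_late,
                 min_separation = min_separation,
                 n_chrom = as.integer(n_chrom),
                 bins_per_chrom = as.integer(bins_per_chrom),
                 bin_size = as.integer(bin_size),
                 n_genes = as.integer(n_genes),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis end to end
#'
#' Executes the pipeline on a synthetic experiment (or a pre-built one):
#' simulate, single-cell RT profiling, pseudo-bulk construction (fraction
#' and pooled routes), and the RT-expression correlation statistics; then
#' assembles a machine-readable report. When the config carries an
#' `out_dir`, all artifacts (fixture, profiles, pseudo-bulk bedGraph,
#' slope TSV, report JSON) are written there.
#'
#' @param config A [run_config()].
#' @param experiment Optional pre-built [simulate_experiment()] result; by
#'   default one is simulated from the config.
#' @param reference Optional reference RT track (data.frame chrom, start,
#'   end, value) to correlate the pseudo-bulk against.
#' @return List with `report` (named list: cells_per_gate, n_cells,
#'   n_mid_s, rep_scores, pseudobulk_slope, signed_rank_p, pearson_r,
#'   early_late, reference_rho, config) plus the intermediate objects
#'   (`experiment`, `profiles`, `pseudobulk`, `pseudobulk_pooled`,
#'   `slopes`, `groups`).
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(seed = 1, bins_per_chrom = 200,
#'                                n_genes = 1000))
#' res$report$n_mid_s
#' }
run_pipeline <- function(config, experiment = NULL, reference = NULL) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")

  log_msg("simulate", "generating synthetic experiment (seed ",
          config$seed, ")")
  if (is.null(experiment)) {
    experiment <- simulate_experiment(
      config$sim, n_chrom = config$n_chrom,
      bins_per_chrom = config$bins_per_chrom,
      bin_size = config$bin_size, n_genes = config$n_genes)
  }
  meta <- experiment$meta
  wcm <- wcm_from_bins(experiment$genome, experiment$counts)

  log_msg("scrt", "profiling ", sum(meta$gate %in% paste0("S", 1:5)),
          " S-phase cells against ", sum(meta$gate == "G1"), " G1 controls")
  profiles <- scrt_profiles(wcm, meta,
                            min_separation = config$min_separation)

  mid_s <- select_mid_s(meta, config$mid_s_gates)
  log_msg("pseudobulk", length(mid_s), " mid-S cells (",
          paste(config$mid_s_gates, collapse = ","), ")")
  pb <- pseudobulk_fraction(profiles, cells = mid_s)
  bl <- g1_baseline(wcm, meta$cell_id[meta$gate == "G1"])
  pb_pooled <- pseudobulk_pooled(wcm, mid_s, bl$baseline, bl$copy)
  ref_rho <- if (!is.null(reference)) {
    correlate_to_reference(pb, reference)$rho
  } else NULL

  log_msg("rtcor", "RT-expression correlation (group size ",
          config$group_size, ")")
  expr <- experiment$expression
  genes <- experiment$genome$genes
  gene_rt <- assign_gene_rt(pb$rt, genes, pb$windows)
  gene_ids <- filter_expressed_genes(expr, config$expressed_log2)
  calls <- expressed_call(expr, config$expressed_log2)
  frac_expr <- rowMeans(calls[, mid_s, drop = FALSE])
  keep <- gene_rt$gene_id %in% gene_ids
  groups <- binned_probability(gene_rt[keep, , drop = FALSE],
                               frac_expr[gene_rt$gene_id[keep]],
                               config$group_size)
  pb_fit <- fit_slope(groups)
  slopes <- slope_table(profiles, expr, genes,
                        group_size = config$group_size,
                        threshold_log2 = config$expressed_log2)
  el <- early_late_expression_test(gene_rt[keep, , drop = FALSE], expr,
                                   threshold = config$early_late)

  report <- list(
    cells_per_gate = as.list(table(factor(meta$gate, levels = gate_labels()))),
    n_cells = nrow(meta),
    n_s_phase = sum(meta$gate %in% paste0("S", 1:5)),
    n_mid_s = length(mid_s),
    rep_scores = as.list(profiles$rep_scores[!is.na(profiles$rep_scores)]),
    pseudobulk_slope = pb_fit$slope,
    pseudobulk_intercept = pb_fit$intercept,
    signed_rank_p = slopes$signed_rank_p,
    pearson_r_slope_repscore = slopes$pearson_r,
    early_late = el[c("median_early", "median_late", "p")],
    reference_rho = ref_rho,
    config = serialize_config(config)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fixture(experiment, file.path(config$out_dir, "fixture"))
    export_profiles(profiles, file.path(config$out_dir, "profiles"))
    ok <- !is.na(pb$rt)
    write_bedgraph(data.frame(chrom = pb$windows$chrom[ok],
                              start = pb$windows$start[ok],
                              end = pb$windows$end[ok], value = pb$rt[ok]),
                   file.path(config$out_dir, "pseudobulk.bedGraph"))
    utils::write.table(slopes$cells,
                       file.path(config$out_dir, "slopes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(groups),
                       file.path(config$out_dir, "groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(report = report, experiment = experiment, profiles = profiles,
       pseudobulk = pb, pseudobulk_pooled = pb_pooled, slopes = slopes,
       groups = groups)
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out$sim$overdispersion <-
    if (is.finite(out$sim$overdispersion)) out$sim$overdispersion else "Inf"
  out
}
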