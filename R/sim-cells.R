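#' Simulate a single cell's true replication states
#'
#' Replication is modeled as a threshold on the timing program: the
#' earliest-replicating fraction `s_fraction` of bins (the bins whose timing
#' exceeds the (1 - s_fraction) quantile) is marked replicated, then each
#' bin's state is flipped independently with probability `flip_noise`.
#' A mid-S cell (s_fraction = 0.5) therefore has ~50% of its genome
#' replicated, and the replicated set is exactly the early half of the
#' timing program when noise is zero. G1 cells force s_fraction = 0, G2
#' cells force 1.
#'
#' @param genome A `genome_model`.
#' @param gate Sorting-gate label, one of [gate_labels()].
#' @param s_fraction Target fraction of the genome replicated, in [0, 1].
#'   Defaults to the gate's canonical fraction ([gate_fractions()]).
#' @param flip_noise Per-bin state flip probability epsilon in [0, 0.5).
#' @param cell_id Cell identifier.
#' @param seed Optional seed (NULL = current RNG state).
#'
#' @return A `cell_truth`: list with `cell_id`, `gate`, `s_fraction` and
#'   `states_true` (integer 0/1 per bin).
#' @export
#' @examples
#' g <- make_genome(sim_config(seed = 1), n_chrom = 1, bins_per_chrom = 200)
#' cell <- simulate_cell(g, "S3", seed = 7)
#' mean(cell$states_true)
simulate_cell <- function(genome, gate,
                          s_fraction = gate_fractions()[[gate]],
                          flip_noise = 0,
                          cell_id = paste0(gate, "_cell"),
                          seed = NULL) {
  assert_that(inherits(genome, "genome_model"), "need a genome_model")
  assert_that(gate %in% gate_labels(),
              "unknown gate label: ", gate, class = "screpli_invalid_argument")
  assert_that(is.numeric(s_fraction) && s_fraction >= 0 && s_fraction <= 1,
              "s_fraction must be in [0, 1]")
  if (gate == "G1") s_fraction <- 0
  if (gate == "G2") s_fraction <- 1
  with_seed(seed)

  timing <- genome$bins$timing
  n <- length(timing)
  n_rep <- round(s_fraction * n)
  # replicated set = top n_rep timing values (timing is a genome-wide rank,
  # so this is the (1 - s)-quantile threshold with exact bin counts)
  states <- integer(n)
  if (n_rep > 0) {
    ord <- order(timing, decreasing = TRUE)
    states[ord[seq_len(n_rep)]] <- 1L
  }
  if (flip_noise > 0) {
    flip <- stats::runif(n) < flip_noise
    states[flip] <- 1L - states[flip]
  }
  structure(list(
    cell_id = cell_id,
    gate = gate,
    s_fraction = s_fraction,
    states_true = states
  ), class = "cell_truth")
}

#' Simulate per-bin read counts for one cell
#'
#' Counts follow the copy-number logic of a replication-sequencing read
#' model: an unreplicated diploid bin has expectation `depth`, a replicated
#' bin carries doubled copy and so has expectation `2 * depth`, and
#' constitutive CNV scales the expectation proportionally
#' (`depth * copy/2 * (1 + state)`). Counts are Poisson by default; a finite
#' `overdispersion` draws negative-binomial counts with that size parameter.
#'
#' @param genome A `genome_model`.
#' @param cell A `cell_truth`.
#' @param depth Expected reads per unreplicated diploid bin; must be > 0.
#' @param overdispersion NB size parameter; Inf = Poisson.
#' @param seed Optional seed (NULL = current RNG state).
#'
#' @return Integer vector of per-bin counts.
#' @export
simulate_counts <- function(genome, cell, depth = 100,
                            overdispersion = Inf, seed = NULL) {
  assert_that(inherits(genome, "genome_model"), "need a genome_model")
  assert_that(inherits(cell, "cell_truth"), "need a cell_truth")
  assert_that(is.numeric(depth) && depth > 0, "depth must be > 0",
              class = "screpli_invalid_argument")
  with_seed(seed)
  mu <- depth * (genome$bins$copy / 2) * (1 + cell$states_true)
  if (is.finite(overdispersion)) {
    stats::rnbinom(length(mu), size = overdispersion, mu = mu)
  } else {
    stats::rpois(length(mu), mu)
  }
}

#' Simulate RT-coupled single-cell gene expression
#'
#' Each gene is "on" in each cell independently with probability
#' `plogis(a + b * rt_gene)` — the logistic link that encodes the
#' early-replicating-genes-are-more-often-expressed structure. On genes emit
#' log2 FPKM from a normal truncated to > 1 (so they always clear the
#' expressed threshold); off genes from a normal truncated to <= 1. The
#' returned matrix stores linear FPKM = 2^(log2 FPKM).
#'
#' @param genome A `genome_model` (provides gene ids and lengths).
#' @param rt_per_gene Numeric vector in [0, 1], one value per gene, in
#'   `genome$genes` order (named vectors are matched by name).
#' @param config A [sim_config()] providing link and emission parameters.
#' @param cell_ids Character vector of cell ids (one column per cell).
#' @param seed Optional seed (NULL = current RNG state).
#'
#' @return An [expression_matrix()] with unit `"FPKM"`.
#' @export
simulate_expression <- function(genome, rt_per_gene, config,
                                cell_ids = "cell1", seed = NULL) {
  assert_that(inherits(genome, "genome_model"), "need a genome_model")
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  genes <- genome$genes
  if (!is.null(names(rt_per_gene))) {
    assert_that(setequal(names(rt_per_gene), genes$gene_id),
                "rt_per_gene names do not match the genome's gene ids",
                class = "screpli_invalid_argument")
    rt_per_gene <- rt_per_gene[genes$gene_id]
  }
  assert_that(length(rt_per_gene) == nrow(genes),
              "need exactly one RT value per gene",
              class = "screpli_invalid_argument")
  with_seed(seed)

  n_g <- nrow(genes)
  n_c <- length(cell_ids)
  p_on <- stats::plogis(config$expr_intercept + config$expr_slope * rt_per_gene)
  on <- matrix(stats::runif(n_g * n_c) < rep(p_on, times = n_c), n_g, n_c)
  log2fpkm <- matrix(NA_real_, n_g, n_c)
  n_on <- sum(on)
  log2fpkm[on] <- rnorm_trunc(n_on, config$expr_on_mean, config$expr_on_sd,
                              lower = 1)
  log2fpkm[!on] <- rnorm_trunc(n_g * n_c - n_on, config$expr_off_mean,
                               config$expr_off_sd, upper = 1)
  values <- 2^log2fpkm
  dimnames(values) <- list(genes$gene_id, cell_ids)
  expression_matrix(values, unit = "FPKM",
                    gene_lengths = stats::setNames(genes$length, genes$gene_id))
}

#' Simulate a full sorted-nuclei experiment
#'
#' Draws the whole study design from one config: a cell per census slot with
#' gate-appropriate replicated fraction, per-bin read counts for every cell,
#' and an RT-coupled expression matrix over the same cells. Everything is a
#' pure function of `config` (and `genome` if supplied).
#'
#' @param config A [sim_config()].
#' @param genome Optional pre-built `genome_model`; by default one is
#'   generated from the config.
#' @param ... Passed to [make_genome()] when `genome` is NULL.
#'
#' @return List with `genome`, `meta` (data.frame cell_id, gate,
#'   s_fraction), `cells` (list of `cell_truth`), `counts` (bins x cells
#'   integer matrix), `states_true` (bins x cells 0/1 matrix), `expression`
#'   (an `expression_matrix`, unit FPKM), and `config`.
#' @export
#' @examples
#' exp <- simulate_experiment(sim_config(seed = 1,
#'   n_cells_per_gate = c(G1 = 2, S3 = 2, G2 = 1)),
#'   n_chrom = 1, bins_per_chrom = 100, n_genes = 200)
#' dim(exp$counts)
simulate_experiment <- function(config, genome = NULL, ...) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  if (is.null(genome)) genome <- make_genome(config, ..., seed = NULL)

  census <- config$n_cells_per_gate
  gates <- rep(names(census), times = census)
  cell_ids <- sprintf("%s_%02d", gates, unlist(lapply(census, seq_len)))
  cells <- vector("list", length(gates))
  counts <- matrix(0L, nrow(genome$bins), length(gates),
                   dimnames = list(NULL, cell_ids))
  states <- matrix(0L, nrow(genome$bins), length(gates),
                   dimnames = list(NULL, cell_ids))
  for (i in seq_along(gates)) {
    cell <- simulate_cell(genome, gates[i], flip_noise = config$flip_noise,
                          cell_id = cell_ids[i], seed = NULL)
    cells[[i]] <- cell
    states[, i] <- cell$states_true
    counts[, i] <- simulate_counts(genome, cell, depth = config$depth,
                                   overdispersion = config$overdispersion,
                                   seed = NULL)
  }
  expr <- if (!is.null(genome$genes) && nrow(genome$genes) > 0) {
    simulate_expression(genome, gene_truth_rt(genome), config,
                        cell_ids = cell_ids, seed = NULL)
  } else NULL
  meta <- data.frame(
    cell_id = cell_ids,
    gate = gates,
    s_fraction = vapply(cells, function(c) c$s_fraction, numeric(1)),
    stringsAsFactors = FALSE
  )
  list(genome = genome, meta = meta, cells = cells, counts = counts,
       states_true = states, expression = expr, config = config)
}
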