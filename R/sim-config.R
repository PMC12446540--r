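#' Sorting-gate labels and their target replicated fractions
#'
#' Nuclei are flow-sorted on DNA content into a G1 gate (2N), five equal
#' S-phase gates S1-S5 of increasing DNA content, and a G2 gate (4N). Each
#' gate maps to a target fraction of the genome already replicated: G1 cells
#' have replicated nothing, G2 cells everything, and the five S gates sit at
#' the centers of five equal quantiles of S-phase progression.
#'
#' @return Named numeric vector mapping gate label to replicated fraction.
#' @export
#' @examples
#' gate_fractions()
gate_fractions <- function() {
  c(G1 = 0, S1 = 0.1, S2 = 0.3, S3 = 0.5, S4 = 0.7, S5 = 0.9, G2 = 1)
}

#' All valid sorting-gate labels
#' @return Character vector of the seven gate labels.
#' @export
gate_labels <- function() names(gate_fractions())

#' Default cell census per sorting gate
#'
#' The default census mirrors a 48-nuclei sorted-plate design: 13 G1 cells,
#' 6/6/5/6/6 cells in S1-S5, and 6 G2 cells (29 S-phase cells, of which 17
#' are mid-S: gates S2-S4).
#'
#' @return Named integer vector of cells per gate.
#' @export
default_census <- function() {
  c(G1 = 13L, S1 = 6L, S2 = 6L, S3 = 5L, S4 = 6L, S5 = 6L, G2 = 6L)
}

#' Simulation configuration for the synthetic sorted-nuclei experiment
#'
#' Bundles every tunable of the generator: the per-gate census, sequencing
#' depth, replication-state label noise, the RT-domain length scale, and the
#' logistic link plus emission parameters tying expression to RT.
#'
#' @param seed Integer seed; the whole fixture is a pure function of the
#'   config (including this seed).
#' @param n_cells_per_gate Named integer vector, cells per gate. Defaults to
#'   [default_census()].
#' @param depth Expected reads per window for an unreplicated diploid window
#'   (Poisson lambda). Must be positive.
#' @param flip_noise Per-window probability that a cell's true replication
#'   state is flipped (mislabel noise epsilon), in [0, 0.5).
#' @param rt_smoothness Moving-average window (in bins) used to smooth the
#'   timing program; sets the replication-domain length scale.
#' @param expr_intercept,expr_slope Logistic link coefficients a and b: a gene
#'   with RT value r is "on" in a cell with probability
#'   `plogis(a + b * r)`. `expr_slope = 0` is the no-association null.
#' @param expr_on_mean,expr_on_sd Normal parameters (log2 FPKM scale) for
#'   "on" genes; emissions are truncated to be > 1 so an on gene always
#'   clears the expressed threshold.
#' @param expr_off_mean,expr_off_sd Normal parameters for "off" genes,
#'   truncated to <= 1.
#' @param overdispersion Negative-binomial size parameter for read counts;
#'   `Inf` (default) gives pure Poisson counts.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$depth
sim_config <- function(seed = 1L,
                       n_cells_per_gate = default_census(),
                       depth = 100,
                       flip_noise = 0.05,
                       rt_smoothness = 10L,
                       expr_intercept = -2,
                       expr_slope = 4,
                       expr_on_mean = 4,
                       expr_on_sd = 1.5,
                       expr_off_mean = -2,
                       expr_off_sd = 1,
                       overdispersion = Inf) {
  assert_that(depth > 0, "depth must be > 0")
  assert_that(is.numeric(flip_noise) && flip_noise >= 0 && flip_noise < 0.5,
              "flip_noise must be in [0, 0.5)")
  assert_that(all(n_cells_per_gate >= 0), "cell counts per gate must be >= 0")
  assert_that(all(names(n_cells_per_gate) %in% gate_labels()),
              "unknown gate label in n_cells_per_gate")
  assert_that(is_count(rt_smoothness), "rt_smoothness must be a positive integer")
  assert_that(overdispersion > 0, "overdispersion must be positive (Inf = Poisson)")
  structure(list(
    seed = as.integer(seed),
    n_cells_per_gate = n_cells_per_gate,
    depth = depth,
    flip_noise = flip_noise,
    rt_smoothness = as.integer(rt_smoothness),
    expr_intercept = expr_intercept,
    expr_slope = expr_slope,
    expr_on_mean = expr_on_mean,
    expr_on_sd = expr_on_sd,
    expr_off_mean = expr_off_mean,
    expr_off_sd = expr_off_sd,
    overdispersion = overdispersion
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config\n")
  cat("  seed:", x$seed, " depth:", x$depth, " flip_noise:", x$flip_noise, "\n")
  cat("  census:", paste(names(x$n_cells_per_gate), x$n_cells_per_gate,
                         sep = "=", collapse = " "), "\n")
  cat("  expression link: plogis(", x$expr_intercept, " + ",
      x$expr_slope, " * RT )\n", sep = "")
  invisible(x)
}
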