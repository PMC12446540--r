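# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop2 <- function(..., class = "screpli_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(cond, ..., class = "screpli_error") {
  if (!isTRUE(cond)) stop2(..., class = class)
  invisible(TRUE)
}

#' Stage-tagged log line on standard error
#' @noRd
log_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# Set the RNG seed only when one is supplied; callers composing several
# stochastic steps seed once and pass seed = NULL downstream.
with_seed <- function(seed) {
  if (!is.null(seed)) {
    assert_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
                "seed must be a single finite number")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Truncated normal draws via inverse-CDF so results are reproducible and
# never loop (rejection-free).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}
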