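#' @keywords internal
"_PACKAGE"

# Mean of a normal variable clipped to [lo, hi] (clipping, not rejection):
# E[min(max(X, lo), hi)] for X ~ N(mu, sd^2).
clipped_normal_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  lo * stats::pnorm(a) + hi * (1 - stats::pnorm(b)) +
    mu * (stats::pnorm(b) - stats::pnorm(a)) +
    sd * (stats::dnorm(a) - stats::dnorm(b))
}

# Truncated-normal sampler via inverse CDF; avoids probability mass piling
# up at the bounds that plain clipping would create.
rtnorm <- function(n, mu, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
  stats::qnorm(u, mu, sd)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stopf("`%s` must be a single number in [%s, %s]", name, lo, hi)
  invisible(x)
}

utils::globalVariables(c("delta_effect", "delta_cost", "lambda", "prob",
                         "curve"))
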