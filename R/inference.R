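#' Adjusted between-group difference from a linear model
#'
#' Estimates the twice-weekly minus once-weekly difference in an outcome by
#' least squares, adjusted for type of psychotherapy (and optionally further
#' covariates such as the baseline outcome or pre-treatment costs) to respect
#' the 2x2 factorial design.
#'
#' @param data Completed (post-imputation) data frame.
#' @param outcome Name of the outcome column.
#' @param arm Name of the 0/1 group indicator column (1 = twice-weekly).
#' @param adjusters Character vector of adjustment covariates.
#' @param conf Confidence level.
#' @return An object of class `effect_estimate`: list with `outcome`,
#'   `estimate` (adjusted mean difference), `se`, `variance`, `ci`, `n` and
#'   `adjusters`.
#' @export
adjusted_difference <- function(data, outcome, arm = "twice",
                                adjusters = "therapy_ipt", conf = 0.95) {
  if (length(unique(data[[arm]])) < 2L)
    stopf("both arms must be present in the data")
  f <- stats::reformulate(c(arm, adjusters), response = outcome)
  fit <- stats::lm(f, data = data)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stopf("rank-deficient design; aliased column(s): %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  est <- cf[[arm]]
  se <- sqrt(stats::vcov(fit)[arm, arm])
  tq <- stats::qt(1 - (1 - conf) / 2, fit$df.residual)
  structure(list(outcome = outcome, estimate = est, se = se, variance = se^2,
                 ci = est + c(-1, 1) * tq * se, n = nrow(data),
                 adjusters = adjusters),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: difference %.4g (SE %.4g), 95%% CI [%.4g, %.4g]\n",
              x$outcome, x$estimate, x$se, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Overall treatment effect on depression over follow-up
#'
#' Estimates the average twice-minus-once difference in BDI-II scores over
#' the post-baseline assessments from a longitudinal linear model with
#' time-specific intercepts, an arm main effect, the baseline BDI-II score
#' as covariate and the therapy-type adjuster. Repeated measurements within
#' a participant are accounted for through a cluster-robust (sandwich)
#' variance with the participant as cluster; this fixed-effects-by-time
#' formulation targets the same estimand as a mixed model with patient and
#' time levels.
#'
#' @param long Completed long data: columns `id`, `time`, the outcome,
#'   `twice`, `therapy_ipt` and `baseline` (baseline outcome value).
#' @param outcome Outcome column name (default `"bdi"`).
#' @param conf Confidence level.
#' @return An `effect_estimate` (estimate = overall arm effect over time).
#' @export
longitudinal_effect <- function(long, outcome = "bdi", conf = 0.95) {
  if (!any(long$time > 0)) stopf("no post-baseline data")
  d <- long[long$time > 0, , drop = FALSE]
  if (length(unique(d$time)) < 2L)
    stopf("need at least two post-baseline timepoints")
  f <- stats::reformulate(c("0", "factor(time)", "twice", "therapy_ipt",
                            "baseline"), response = outcome)
  fit <- stats::lm(f, data = d)
  V <- sandwich::vcovCL(fit, cluster = d$id)
  est <- stats::coef(fit)[["twice"]]
  se <- sqrt(V["twice", "twice"])
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(outcome = outcome, estimate = est, se = se, variance = se^2,
                 ci = est + c(-1, 1) * zq * se,
                 n = length(unique(d$id)),
                 adjusters = c("time", "therapy_ipt", "baseline")),
            class = "effect_estimate")
}

# adjusted percentile indices for BCa / BC intervals
.bca_alpha <- function(z0, a, probs) {
  zq <- stats::qnorm(probs)
  stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Nonparametric bootstrap of a statistic over resampled rows with the BCa
#' interval: the bias-correction constant comes from the proportion of
#' replicates below the point estimate, the acceleration from the jackknife
#' skewness, and the interval endpoints are the correspondingly adjusted
#' percentiles of the replicate distribution (linear interpolation between
#' order statistics). Setting `accelerated = FALSE` fixes the acceleration
#' at 0, i.e. a bias-corrected percentile interval.
#'
#' @param data Vector, or data frame resampled by rows.
#' @param statistic Function of the resampled data returning a scalar.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @param accelerated If `FALSE`, acceleration is set to 0 (plain bias
#'   correction).
#' @param strata Optional factor: resampling is done within strata, which
#'   preserves e.g. arm sizes.
#' @param exhaustive If `TRUE`, all `n^n` equally likely resamples are
#'   enumerated instead of Monte-Carlo sampled; only sensible for very small
#'   samples (n <= 8).
#' @return List with `t0` (point estimate), `ci`, `z0`, `a`, `replicates`
#'   and `degenerate` (TRUE when all replicates are equal, in which case the
#'   interval collapses to the point).
#' @export
bca_bootstrap <- function(data, statistic, B = 5000L, seed = 1L,
                          conf = 0.95, accelerated = TRUE, strata = NULL,
                          exhaustive = FALSE) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  take <- function(d, i) if (is.data.frame(d)) d[i, , drop = FALSE] else d[i]
  t0 <- statistic(data)
  if (exhaustive) {
    if (n > 8L) stopf("exhaustive enumeration is limited to n <= 8")
    idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    reps <- apply(idx, 1L, function(i) statistic(take(data, i)))
  } else {
    if (B < 100L) stopf("B must be at least 100")
    resample_idx <- if (is.null(strata)) {
      function() sample.int(n, n, replace = TRUE)
    } else {
      groups <- split(seq_len(n), strata)
      function() unlist(lapply(groups, function(g)
        g[sample.int(length(g), length(g), replace = TRUE)]),
        use.names = FALSE)
    }
    set.seed(seed)
    reps <- vapply(seq_len(B),
                   function(b) statistic(take(data, resample_idx())),
                   numeric(1))
  }
  if (all(reps == reps[1])) {
    return(list(t0 = t0, ci = c(reps[1], reps[1]), z0 = 0, a = 0,
                replicates = reps, degenerate = TRUE))
  }
  z0 <- stats::qnorm(pmin(pmax(mean(reps < t0) + 0.5 * mean(reps == t0),
                               1 / (2 * B)), 1 - 1 / (2 * B)))
  a <- 0
  if (accelerated) {
    jack <- vapply(seq_len(n), function(i) statistic(take(data, -i)),
                   numeric(1))
    d <- mean(jack) - jack
    denom <- sum(d^2)^1.5
    a <- if (denom > 0) sum(d^3) / (6 * denom) else 0
  }
  probs <- .bca_alpha(z0, a, c((1 - conf) / 2, 1 - (1 - conf) / 2))
  ci <- unname(stats::quantile(reps, probs, type = 7))
  list(t0 = t0, ci = ci, z0 = z0, a = a, replicates = reps,
       degenerate = FALSE)
}

#' Bootstrap cost-effect pairs across all imputed datasets
#'
#' Within each completed dataset, participants are resampled (stratified by
#' arm, so arm sizes are preserved and cost-effect pairs are resampled
#' jointly) `B` times; each resample yields an adjusted cost difference and
#' effect difference from the supplied statistic. The pairs are concatenated
#' across the m imputed datasets into a bootstrap cloud for the
#' cost-effectiveness plane and acceptability curves, and scalar estimates
#' are pooled across imputations by Rubin's rules with the per-imputation
#' bootstrap variance as within-imputation variance.
#'
#' @param imputed An `imputed_set`.
#' @param statistic Function of a completed data frame returning a named
#'   numeric vector, by convention `c(delta_cost = ..., delta_effect = ...)`
#'   (any length >= 1 is accepted).
#' @param B Replicates per imputed dataset.
#' @param seed Integer seed (per-imputation substreams `seed + i`).
#' @param arm Column with the 0/1 group indicator used for stratified
#'   resampling.
#' @return An object of class `bootstrap_cloud`: data frame with columns
#'   `imputation`, `replicate` and one column per statistic component;
#'   attributes `point` (per-component pooled estimate via [rubin_pool()]),
#'   `per_imputation` (point estimates per imputation) and `B`.
#' @export
mi_bootstrap <- function(imputed, statistic, B = 5000L, seed = 1L,
                         arm = "twice") {
  stopifnot(inherits(imputed, "imputed_set"))
  clouds <- vector("list", imputed$m)
  points <- vector("list", imputed$m)
  for (i in seq_len(imputed$m)) {
    d <- imputed$datasets[[i]]
    points[[i]] <- statistic(d)
    groups <- split(seq_len(nrow(d)), d[[arm]])
    set.seed(seed + i)
    reps <- t(vapply(seq_len(B), function(b) {
      idx <- unlist(lapply(groups, function(g)
        g[sample.int(length(g), length(g), replace = TRUE)]),
        use.names = FALSE)
      statistic(d[idx, , drop = FALSE])
    }, numeric(length(points[[i]]))))
    clouds[[i]] <- data.frame(imputation = i, replicate = seq_len(B), reps)
  }
  cloud <- do.call(rbind, clouds)
  comp <- names(points[[1]])
  pooled <- lapply(comp, function(p) {
    est <- vapply(points, `[[`, numeric(1), p)
    va <- vapply(clouds, function(cl) stats::var(cl[[p]]), numeric(1))
    rubin_pool(est, va)
  })
  names(pooled) <- comp
  structure(cloud, class = c("bootstrap_cloud", "data.frame"),
            point = pooled,
            per_imputation = do.call(rbind, points), B = B, seed = seed)
}

#' Write a bootstrap cloud to CSV
#' @param cloud A `bootstrap_cloud`.
#' @param path Output path.
#' @export
write_cloud <- function(cloud, path) {
  utils::write.csv(as.data.frame(cloud), path, row.names = FALSE)
  invisible(path)
}
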