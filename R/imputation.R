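#' Specification for multiple imputation by chained equations
#'
#' Controls the chained-equations sampler: which variables to impute, which
#' variables predict which, the predictive-mean-matching donor pool, the
#' number of sweeps per imputation, and the adaptive imputation count used by
#' [adapt_m()] (starting at `m_initial` and increased until the fraction of
#' missing information of every monitored parameter falls below
#' `fmi_threshold`).
#'
#' @param variables Character vector of variables to impute; `NULL` means
#'   every variable with missing values.
#' @param predictors Named list: for each imputed variable, the character
#'   vector of predictor columns. `NULL` builds a default from
#'   [default_predictors()].
#' @param k Donor pool size for predictive mean matching.
#' @param sweeps Chained-equation sweeps per imputation.
#' @param m_initial,m_max Starting and maximum number of imputations.
#' @param fmi_threshold Target fraction of missing information (default 0.05:
#'   imputations are added until FMI < 5%).
#' @param strata Column used to stratify imputation (models fitted separately
#'   per stratum); default `"twice"`, i.e. by intervention group. `NULL`
#'   pools the strata and adds the group indicator as a predictor.
#' @param seed Master seed; imputation `i` uses substream seed `seed + i`, so
#'   extending `m` preserves earlier imputations.
#' @return An object of class `imputation_spec`.
#' @export
imputation_spec <- function(variables = NULL, predictors = NULL, k = 5L,
                            sweeps = 10L, m_initial = 5L, m_max = 64L,
                            fmi_threshold = 0.05, strata = "twice",
                            seed = 1L) {
  assert_number(k, "k", 1)
  assert_number(sweeps, "sweeps", 1)
  assert_number(m_initial, "m_initial", 2)
  assert_number(m_max, "m_max", m_initial)
  assert_number(fmi_threshold, "fmi_threshold", 1e-12, 1)
  structure(list(variables = variables, predictors = predictors,
                 k = as.integer(k), sweeps = as.integer(sweeps),
                 m_initial = as.integer(m_initial), m_max = as.integer(m_max),
                 fmi_threshold = fmi_threshold, strata = strata,
                 seed = as.integer(seed)),
            class = "imputation_spec")
}

#' Default predictor sets for the trial analysis frame
#'
#' The imputation model for each variable contains the baseline covariates
#' (therapy type, age, gender, education, employment, baseline BDI-II,
#' utility, functioning scores and pre-treatment costs — the covariates
#' related to treatment group, dropout and outcome), the same variable at the
#' other assessment times or periods, and the concurrent depression score.
#' When imputation is not stratified by group, the group indicator is added.
#'
#' @param frame Analysis frame as built by [build_analysis_frame()].
#' @param variables Variables to impute.
#' @param stratified Whether imputation is run separately per arm.
#' @return Named list of predictor vectors.
#' @export
default_predictors <- function(frame, variables, stratified = TRUE) {
  base <- intersect(c("therapy_ipt", "age", "female", "education", "employed",
                      "bdi_0", "utility_0", "pfs_0", "sfs_0", "baseline_cost"),
                    names(frame))
  if (!stratified) base <- c("twice", base)
  out <- lapply(variables, function(v) {
    stem <- sub("_[0-9]+$", "", v)
    suffix <- sub("^.*_", "", v)
    family <- setdiff(grep(paste0("^", stem, "_[0-9]+$"), names(frame),
                           value = TRUE), v)
    conc <- if (grepl("^cost_", v)) {
      per <- suppressWarnings(as.integer(suffix))
      paste0("bdi_", 3L * per)
    } else paste0("bdi_", suffix)
    unique(setdiff(intersect(c(base, family, conc), names(frame)), v))
  })
  stats::setNames(out, variables)
}

# Bayesian linear regression draw + type-1 predictive mean matching for one
# variable, following the standard chained-equations recipe. Returns imputed
# values (all drawn from the observed support) and the predictors dropped for
# collinearity.
.pmm_draw <- function(y, X, mis, k) {
  obs <- !mis
  Xo <- X[obs, , drop = FALSE]
  qr_o <- qr(Xo)
  dropped <- character(0)
  if (qr_o$rank < ncol(Xo)) {
    keep <- qr_o$pivot[seq_len(qr_o$rank)]
    dropped <- colnames(Xo)[-keep]
    X <- X[, keep, drop = FALSE]
    Xo <- Xo[, keep, drop = FALSE]
    qr_o <- qr(Xo)
  }
  yo <- y[obs]
  beta_hat <- qr.coef(qr_o, yo)
  res <- yo - Xo %*% beta_hat
  df <- max(length(yo) - ncol(Xo), 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1L, df)
  R <- qr.R(qr_o)
  beta_star <- beta_hat + backsolve(R, stats::rnorm(ncol(Xo))) * sqrt(sigma2)
  yhat_obs <- drop(Xo %*% beta_hat)
  yhat_mis <- drop(X[mis, , drop = FALSE] %*% beta_star)
  # k nearest donors on predicted mean, searched in a sorted window
  o <- order(yhat_obs)
  ys <- yhat_obs[o]
  yo_s <- yo[o]
  n_obs <- length(ys)
  kk <- min(k, n_obs)
  imp <- vapply(yhat_mis, function(yh) {
    pos <- findInterval(yh, ys)
    win <- max(1L, pos - kk + 1L):min(n_obs, pos + kk)
    d <- abs(ys[win] - yh)
    donors <- win[order(d)[seq_len(kk)]]
    yo_s[donors[sample.int(kk, 1L)]]
  }, numeric(1))
  list(imputed = imp, dropped = dropped)
}

# One completed dataset: chained equations over all imputed variables.
# Works on a numeric matrix internally; the frame's columns must be numeric.
.impute_once <- function(frame, spec, variables, predictors, seed) {
  set.seed(seed)
  M <- data.matrix(frame)
  strata <- if (is.null(spec$strata)) rep(1L, nrow(frame))
            else frame[[spec$strata]]
  strata_rows <- split(seq_len(nrow(M)), strata)
  miss <- lapply(variables, function(v) is.na(frame[[v]]))
  names(miss) <- variables
  dropped_log <- character(0)
  # initial fill: random draws from the observed values (within stratum)
  for (v in variables) {
    for (rows in strata_rows) {
      r <- rows[miss[[v]][rows]]
      pool <- M[rows[!miss[[v]][rows]], v]
      if (!length(pool)) pool <- M[!miss[[v]], v]
      if (!length(pool)) stopf("variable `%s` has no observed values", v)
      if (length(r)) M[r, v] <- pool[sample.int(length(pool), length(r),
                                                replace = TRUE)]
    }
  }
  for (sw in seq_len(spec$sweeps)) {
    for (v in variables) {
      if (!any(miss[[v]])) next
      for (rows in strata_rows) {
        mis_s <- miss[[v]][rows]
        if (!any(mis_s)) next
        X <- cbind(1, M[rows, predictors[[v]], drop = FALSE])
        colnames(X) <- c("(Intercept)", predictors[[v]])
        d <- .pmm_draw(M[rows, v], X, mis_s, spec$k)
        M[rows[mis_s], v] <- d$imputed
        if (length(d$dropped))
          dropped_log <- union(dropped_log, paste0(v, ": ", d$dropped))
      }
    }
  }
  comp <- frame
  for (v in variables) comp[[v]] <- M[, v]
  attr(comp, "dropped_predictors") <- dropped_log
  comp
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Fills missing values in the analysis frame by iterated univariate
#' imputation: each variable with missing entries is regressed on its
#' predictors (current completed values), regression parameters are drawn
#' from their posterior, and each missing entry receives the observed value
#' of a donor sampled among the `k` cases whose predicted means are closest
#' to the target's predicted mean. Predictive mean matching keeps imputed
#' values inside the observed support, which suits the heavily skewed cost
#' distributions. Models are fitted separately per intervention group by
#' default.
#'
#' @param frame Data frame to impute (typically from
#'   [build_analysis_frame()]). All imputed variables must be numeric.
#' @param spec An [imputation_spec()].
#' @param m Number of imputations; defaults to `spec$m_initial`. Use
#'   [adapt_m()] for the FMI-driven choice of m.
#' @return An object of class `imputed_set`: list with `datasets` (m
#'   completed data frames), `m`, `variables`, `spec` and a log of predictors
#'   dropped for collinearity.
#' @export
mice_pmm <- function(frame, spec = imputation_spec(), m = spec$m_initial) {
  stopifnot(is.data.frame(frame), inherits(spec, "imputation_spec"))
  variables <- spec$variables %||%
    names(frame)[vapply(frame, anyNA, logical(1))]
  bad <- variables[!vapply(frame[variables], is.numeric, logical(1))]
  if (length(bad))
    stopf("imputed variables must be numeric: %s", paste(bad, collapse = ", "))
  for (v in variables)
    if (all(is.na(frame[[v]])))
      stopf("variable `%s` has no observed values", v)
  predictors <- spec$predictors %||%
    default_predictors(frame, variables, stratified = !is.null(spec$strata))
  datasets <- lapply(seq_len(m), function(i)
    .impute_once(frame, spec, variables, predictors, seed = spec$seed + i))
  dropped <- unique(unlist(lapply(datasets, attr, "dropped_predictors")))
  if (length(dropped))
    warning("predictors dropped for collinearity: ",
            paste(dropped, collapse = "; "), call. = FALSE)
  structure(list(datasets = datasets, m = m, variables = variables,
                 predictors = predictors, spec = spec,
                 dropped_predictors = dropped),
            class = "imputed_set")
}

#' @export
print.imputed_set <- function(x, ...) {
  cat(sprintf("Multiply imputed set: m = %d, %d imputed variable(s)\n",
              x$m, length(x$variables)))
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines m per-imputation point estimates and squared standard errors:
#' the pooled estimate is the mean of the estimates, the total variance is
#' `T = W + (1 + 1/m) B` with `W` the mean within-imputation variance and
#' `B` the between-imputation variance, the confidence interval uses the t
#' reference with Rubin's degrees of freedom, and the fraction of missing
#' information (FMI) follows the standard definition
#' `(r + 2/(df + 3)) / (r + 1)` with relative variance increase
#' `r = (1 + 1/m) B / W`.
#'
#' @param estimates Numeric vector of per-imputation point estimates.
#' @param variances Per-imputation squared standard errors, same length.
#' @param conf Confidence level.
#' @return An object of class `pooled_estimate` with fields `estimate`, `W`,
#'   `B`, `T`, `se`, `fmi`, `df`, `ci` and `m`. With m = 1 the single
#'   estimate passes through with `T = W` and FMI 0.
#' @export
#' @examples
#' p <- rubin_pool(c(1, 2, 3), c(1, 1, 1))
#' c(p$estimate, p$W, p$B, p$T)  # 2, 1, 1, 7/3
rubin_pool <- function(estimates, variances, conf = 0.95) {
  if (length(estimates) != length(variances))
    stopf("`estimates` and `variances` must have the same length")
  m <- length(estimates)
  qbar <- mean(estimates)
  W <- mean(variances)
  if (m == 1L) {
    se <- sqrt(W)
    ci <- qbar + c(-1, 1) * stats::qnorm(1 - (1 - conf) / 2) * se
    return(structure(list(estimate = qbar, W = W, B = 0, T = W, se = se,
                          fmi = 0, df = Inf, ci = ci, m = 1L, conf = conf),
                     class = "pooled_estimate"))
  }
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  se <- sqrt(Tv)
  if (B <= 0 || Tv <= 0) {
    df <- Inf; fmi <- 0
  } else {
    r <- (1 + 1 / m) * B / W
    df <- (m - 1) * (1 + 1 / r)^2
    fmi <- (r + 2 / (df + 3)) / (r + 1)
  }
  tq <- stats::qt(1 - (1 - conf) / 2, df)
  structure(list(estimate = qbar, W = W, B = B, T = Tv, se = se,
                 fmi = fmi, df = df, ci = qbar + c(-1, 1) * tq * se,
                 m = m, conf = conf),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate %.4g (SE %.4g), %g%% CI [%.4g, %.4g], m = %d, FMI = %.3f\n",
              x$estimate, x$se, 100 * x$conf, x$ci[1], x$ci[2], x$m, x$fmi))
  invisible(x)
}

#' Choose the number of imputations adaptively from the FMI
#'
#' Starts at `spec$m_initial` imputations and doubles m — reusing the
#' already-computed imputations, whose substream seeds depend only on the
#' imputation index — until the fraction of missing information of every
#' monitored parameter is below `spec$fmi_threshold`, or `spec$m_max` is
#' reached (with a warning).
#'
#' @param frame Data frame with missing values.
#' @param spec An [imputation_spec()].
#' @param analysis Function taking a completed data frame and returning a
#'   list/data frame with numeric fields `estimate` and `variance` per
#'   monitored parameter (a named list of such pairs, or a two-column matrix
#'   with rownames).
#' @return An `imputed_set` with the final m; the FMI trace is attached as
#'   attribute `fmi_trace` (one row per tried m).
#' @export
adapt_m <- function(frame, spec, analysis) {
  stopifnot(inherits(spec, "imputation_spec"), is.function(analysis))
  variables <- spec$variables %||%
    names(frame)[vapply(frame, anyNA, logical(1))]
  if (!length(variables)) {
    imp <- mice_pmm(frame, spec, m = spec$m_initial)
    attr(imp, "fmi_trace") <- data.frame(m = spec$m_initial, max_fmi = 0)
    return(imp)
  }
  predictors <- spec$predictors %||%
    default_predictors(frame, variables, stratified = !is.null(spec$strata))
  spec$variables <- variables
  spec$predictors <- predictors

  datasets <- list()
  stats_per_imp <- list()
  m <- spec$m_initial
  trace <- NULL
  repeat {
    for (i in seq.int(length(datasets) + 1L, m)) {
      datasets[[i]] <- .impute_once(frame, spec, variables, predictors,
                                    seed = spec$seed + i)
      stats_per_imp[[i]] <- analysis(datasets[[i]])
    }
    params <- names(stats_per_imp[[1]])
    fmis <- vapply(params, function(p) {
      est <- vapply(stats_per_imp, function(s) s[[p]]$estimate, numeric(1))
      va <- vapply(stats_per_imp, function(s) s[[p]]$variance, numeric(1))
      rubin_pool(est, va)$fmi
    }, numeric(1))
    trace <- rbind(trace, data.frame(m = m, max_fmi = max(fmis)))
    if (max(fmis) < spec$fmi_threshold || m >= spec$m_max) break
    m <- min(2L * m, spec$m_max)
  }
  if (max(trace$max_fmi[nrow(trace)]) >= spec$fmi_threshold)
    warning(sprintf("FMI %.3f still above threshold %.3f at m_max = %d",
                    trace$max_fmi[nrow(trace)], spec$fmi_threshold, m),
            call. = FALSE)
  out <- structure(list(datasets = datasets, m = m, variables = variables,
                        predictors = predictors, spec = spec,
                        dropped_predictors = unique(unlist(
                          lapply(datasets, attr, "dropped_predictors")))),
                   class = "imputed_set")
  attr(out, "fmi_trace") <- trace
  out
}
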