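#' Incremental cost-effectiveness ratio
#'
#' Divides the (pooled) difference in costs by the difference in effects and
#' labels the quadrant of the cost-effectiveness plane the point lies in, so
#' the sign of the ratio can be interpreted (the same negative ICER can mean
#' dominance or being dominated).
#'
#' @param delta_cost Incremental cost in euro (comparator arm minus control).
#' @param delta_effect Incremental effect in the outcome's units, oriented so
#'   that improvement is positive.
#' @return List with `icer` (`NA` with a message when `delta_effect` is 0)
#'   and `quadrant` (`"NE"`, `"SE"`, `"SW"` or `"NW"`; boundary points count
#'   as favourable/higher-cost).
#' @export
#' @examples
#' icer(2276, -1.36)  # -1673.5, NW quadrant in oriented units
icer <- function(delta_cost, delta_effect) {
  q <- if (delta_effect >= 0) {
    if (delta_cost >= 0) "NE" else "SE"
  } else {
    if (delta_cost >= 0) "NW" else "SW"
  }
  if (delta_effect == 0)
    return(list(icer = NA_real_, quadrant = q,
                note = "undefined: zero effect difference"))
  list(icer = delta_cost / delta_effect, quadrant = q)
}

#' Quadrant proportions of a bootstrap cost-effect cloud
#'
#' The fraction of bootstrapped cost-effect pairs in each quadrant of the
#' cost-effectiveness plane, after orienting the effect axis so clinical
#' improvement is positive (for depression scores, where decreases are
#' improvements, pass `effect_direction = "lower_better"`). Boundary pairs
#' count as favourable (effect >= 0) and higher-cost (cost >= 0).
#'
#' @param cloud A `bootstrap_cloud` or data frame with columns `delta_cost`
#'   and `delta_effect`.
#' @param effect_direction `"higher_better"` (QALY, functioning scores) or
#'   `"lower_better"` (depression severity).
#' @return Named proportions `NE`, `SE`, `SW`, `NW` summing to 1.
#' @export
quadrant_proportions <- function(cloud,
                                 effect_direction = c("higher_better",
                                                      "lower_better")) {
  effect_direction <- match.arg(effect_direction)
  if (!nrow(cloud)) stopf("empty bootstrap cloud")
  e <- cloud$delta_effect * if (effect_direction == "lower_better") -1 else 1
  cst <- cloud$delta_cost
  c(NE = mean(e >= 0 & cst >= 0),
    SE = mean(e >= 0 & cst < 0),
    SW = mean(e < 0 & cst < 0),
    NW = mean(e < 0 & cst >= 0))
}

#' Net monetary benefit
#'
#' `lambda * delta_effect - delta_cost`: the monetary value of the health
#' gained at willingness-to-pay `lambda` per effect unit, minus the extra
#' cost. Positive NMB means cost-effective at that ceiling ratio.
#'
#' @param delta_effect Incremental effect, improvement oriented positive.
#' @param delta_cost Incremental cost in euro.
#' @param lambda Ceiling ratio (euro per effect unit), non-negative;
#'   vectorised.
#' @return Net monetary benefit in euro.
#' @export
nmb <- function(delta_effect, delta_cost, lambda) {
  if (any(lambda < 0)) stopf("ceiling ratios must be non-negative")
  lambda * delta_effect - delta_cost
}

#' Default ceiling-ratio grid
#'
#' 0 to 100 000 euro per effect unit in 251 steps, always including the
#' conventional reference ratios (1000 per point of a clinical scale; 20 000,
#' 23 000, 34 000 and 50 000 per QALY).
#'
#' @param upper Upper end of the grid.
#' @return Increasing numeric vector of ceiling ratios.
#' @export
lambda_grid <- function(upper = 1e5) {
  sort(unique(c(seq(0, upper, length.out = 251),
                c(1000, 20000, 23000, 34000, 50000))))
}

#' Cost-effectiveness acceptability curve from pooled net monetary benefit
#'
#' The primary CEAC method: at each ceiling ratio, the net monetary benefit
#' and its variance are computed per imputation from that imputation's
#' cost and effect differences and their bootstrap covariance
#' (`var(NMB) = lambda^2 var(dE) + var(dC) - 2 lambda cov`), pooled by
#' Rubin's rules, and the probability of cost-effectiveness is the standard
#' normal CDF of pooled NMB / pooled SE.
#'
#' @param per_imp Data frame with one row per imputation: columns
#'   `delta_effect`, `delta_cost`, `var_effect`, `var_cost`, `cov_ce`
#'   (effects oriented so improvement is positive).
#' @param lambdas Ceiling-ratio grid.
#' @return An object of class `ceac_curve`: data frame `(lambda, prob)` with
#'   attribute `method = "parametric-NMB"`.
#' @export
ceac_parametric <- function(per_imp, lambdas = lambda_grid()) {
  need <- c("delta_effect", "delta_cost", "var_effect", "var_cost", "cov_ce")
  if (!all(need %in% names(per_imp)))
    stopf("`per_imp` needs columns: %s", paste(need, collapse = ", "))
  prob <- vapply(lambdas, function(l) {
    est <- l * per_imp$delta_effect - per_imp$delta_cost
    va <- l^2 * per_imp$var_effect + per_imp$var_cost - 2 * l * per_imp$cov_ce
    p <- rubin_pool(est, pmax(va, 0))
    if (p$se == 0) as.numeric(p$estimate >= 0)
    else stats::pnorm(p$estimate / p$se)
  }, numeric(1))
  structure(data.frame(lambda = lambdas, prob = prob),
            class = c("ceac_curve", "data.frame"), method = "parametric-NMB")
}

#' Cost-effectiveness acceptability curve from the bootstrap cloud
#'
#' Validation counterpart of [ceac_parametric()]: at each ceiling ratio, the
#' fraction of bootstrapped cost-effect pairs with positive net monetary
#' benefit. Its value at lambda = 0 equals the proportion of pairs with cost
#' savings (SE + SW quadrant mass) and its large-lambda limit the proportion
#' with favourable effects (NE + SE mass).
#'
#' @param cloud Data frame with `delta_cost` and `delta_effect` columns
#'   (effects oriented so improvement is positive).
#' @param lambdas Ceiling-ratio grid.
#' @return A `ceac_curve` with attribute `method = "cloud-proportion"`.
#' @export
ceac_cloud <- function(cloud, lambdas = lambda_grid()) {
  if (!nrow(cloud)) stopf("empty bootstrap cloud")
  prob <- vapply(lambdas, function(l)
    mean(l * cloud$delta_effect - cloud$delta_cost > 0), numeric(1))
  structure(data.frame(lambda = lambdas, prob = prob),
            class = c("ceac_curve", "data.frame"), method = "cloud-proportion")
}

#' Plot the cost-effectiveness plane
#'
#' @param cloud Data frame with `delta_effect` and `delta_cost` (oriented).
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(cloud, xlab = "incremental effect",
                          ylab = "incremental cost (EUR)") {
  ggplot2::ggplot(as.data.frame(cloud),
                  ggplot2::aes(x = delta_effect, y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot one or more cost-effectiveness acceptability curves
#'
#' @param ... Named `ceac_curve` objects.
#' @return A ggplot object.
#' @export
plot_ceac <- function(...) {
  curves <- list(...)
  nm <- names(curves) %||% paste0("curve", seq_along(curves))
  df <- do.call(rbind, Map(function(cv, n)
    cbind(as.data.frame(cv), curve = n), curves, nm))
  ggplot2::ggplot(df, ggplot2::aes(x = lambda, y = prob, colour = curve)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "ceiling ratio (EUR per effect unit)",
                  y = "probability cost-effective") +
    ggplot2::theme_minimal()
}
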