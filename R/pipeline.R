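# category tags used in the wide analysis frame
.cost_stems <- c(mental_healthcare = "mh", other_healthcare = "oh",
                 medication = "med", informal_care = "inf",
                 absenteeism_paid = "abp", absenteeism_unpaid = "abu",
                 presenteeism = "pres")

#' Build the wide per-participant analysis frame
#'
#' Reshapes a trial dataset and its cost breakdown into one row per
#' participant: baseline covariates, clinical outcomes per assessment time
#' (columns `bdi_3`, `utility_12`, ...), per-period per-category costs
#' (columns `cost_mh_1` ... `cost_pres_4`), intervention cost per period
#' (`int_1` ... — complete by design, attendance is administrative data) and
#' the pre-treatment societal cost (`baseline_cost`). Missing assessments
#' appear as `NA` and are the imputation targets; costs are imputed at
#' period-by-category level so aggregation to annual totals happens after
#' imputation. If utilities are absent but EQ-5D-5L profiles present, the
#' value set converts them.
#'
#' @param data A `trial_data` object.
#' @param costs A `cost_breakdown` from [aggregate_costs()].
#' @param vset Value set used when only state profiles are available.
#' @return Data frame, one row per participant, with attribute `timepoints`.
#' @export
build_analysis_frame <- function(data, costs, vset = example_value_set()) {
  stopifnot(inherits(data, "trial_data"), inherits(costs, "cost_breakdown"))
  b <- data$baseline
  long <- data$long
  tp <- sort(unique(long$time_m))

  if (all(is.na(long$utility)) || anyNA(long$utility)) {
    st <- !is.na(long$eq5d5l_state) & is.na(long$utility)
    if (any(st))
      long$utility[st] <- utility_from_state(long$eq5d5l_state[st], vset)
  }

  frame <- data.frame(
    id = b$id,
    twice = as.integer(b$frequency_arm == "twice"),
    therapy_ipt = as.integer(b$therapy == "IPT"),
    site = b$site, age = b$age, female = b$female,
    education = b$education, employed = b$employed,
    hours_day = b$hours_day, sessions_attended = b$sessions_attended
  )
  for (t in tp) {
    r <- long[long$time_m == t, ]
    i <- match(frame$id, r$id)
    for (v in c("bdi", "utility", "pfs", "sfs"))
      frame[[paste0(v, "_", t)]] <- r[[v]][i]
  }
  per <- costs$periods
  for (p in setdiff(sort(unique(per$period)), 0L)) {
    r <- per[per$period == p, ]
    i <- match(frame$id, r$id)
    frame[[paste0("int_", p)]] <- r$intervention[i]
    for (cc in names(.cost_stems))
      frame[[paste0("cost_", .cost_stems[[cc]], "_", p)]] <- r[[cc]][i]
  }
  base_per <- per[per$period == 0L, ]
  frame$baseline_cost <- base_per$societal_total[match(frame$id, base_per$id)]
  attr(frame, "timepoints") <- tp
  frame
}

# vectorised QALY over the frame's utility columns (times in years)
frame_qaly <- function(frame, tp = attr(frame, "timepoints")) {
  yrs <- tp / 12
  u <- as.matrix(frame[paste0("utility_", tp)])
  dt <- diff(yrs)
  mid <- (u[, -1, drop = FALSE] + u[, -ncol(u), drop = FALSE]) / 2
  drop(mid %*% dt)
}

# annual (periods >= 1) cost totals under a perspective
frame_annual_cost <- function(frame, perspective = "societal") {
  stems <- if (perspective == "healthcare") c("mh", "oh", "med")
           else unname(.cost_stems)
  cols <- c(grep("^int_", names(frame), value = TRUE),
            unlist(lapply(stems, function(s)
      grep(paste0("^cost_", s, "_"), names(frame), value = TRUE))))
  rowSums(as.matrix(frame[cols]))
}

# fast OLS arm coefficient: y ~ 1 + twice + adjusters (column 2 = twice)
.arm_coef <- function(y, X) {
  stats::lm.fit(X, y)$coefficients[[2L]]
}

# per-completed-frame (delta_cost, delta_<outcome>...) statistic used for
# bootstrapping; built once per configuration for speed
.make_stat <- function(config, tp) {
  fu <- setdiff(tp, 0)
  function(d) {
    Xc <- cbind(1, d$twice, d$therapy_ipt,
                if (config$baseline_adjust) d$baseline_cost)
    out <- c(delta_cost = .arm_coef(frame_annual_cost(d, config$perspective),
                                    Xc))
    X2 <- cbind(1, d$twice, d$therapy_ipt)
    if ("QALY" %in% config$outcomes)
      out["delta_QALY"] <- .arm_coef(frame_qaly(d, tp), X2)
    if ("PFS" %in% config$outcomes)
      out["delta_PFS"] <- .arm_coef(d[[paste0("pfs_", max(tp))]], X2)
    if ("SFS" %in% config$outcomes)
      out["delta_SFS"] <- .arm_coef(d[[paste0("sfs_", max(tp))]], X2)
    if ("BDI" %in% config$outcomes) {
      y <- unlist(d[paste0("bdi_", fu)], use.names = FALSE)
      n <- nrow(d)
      tdum <- stats::model.matrix(~ 0 + factor(rep(fu, each = n)))
      Xl <- cbind(tdum, rep(d$twice, length(fu)),
                  rep(d$therapy_ipt, length(fu)), rep(d$bdi_0, length(fu)))
      out["delta_BDI"] <- stats::lm.fit(Xl, y)$coefficients[[length(fu) + 1L]]
    }
    out
  }
}

#' Configuration of a full cost-effectiveness analysis run
#'
#' @param data Either a [trial_config()] (synthetic data are generated and
#'   missingness injected) or a `trial_data` object (e.g. from
#'   [read_trial_csv()]).
#' @param perspective `"societal"` (all cost components) or `"healthcare"`.
#' @param approach Valuation of paid absenteeism: `"friction"` or
#'   `"human_capital"`.
#' @param outcomes Effect outcomes to analyse, subset of
#'   `c("QALY", "BDI", "PFS", "SFS")`.
#' @param outlier_threshold If non-`NULL`, participants whose societal costs
#'   reach this amount (euro) in any 3-month follow-up period have their
#'   questionnaire-based period costs recoded as missing before imputation.
#' @param outlier_scope `"all_periods"` recodes all four follow-up periods of
#'   a flagged participant (conservative default); `"offending"` only the
#'   period(s) at or above the threshold.
#' @param baseline_adjust Add pre-treatment 3-month societal costs as an
#'   adjuster in the cost model.
#' @param B Bootstrap replicates per imputed dataset (5000 for definitive
#'   runs; reduce for exploration).
#' @param m_initial,m_max,fmi_threshold Imputation policy, see
#'   [imputation_spec()].
#' @param lambdas Ceiling-ratio grid for the acceptability curves.
#' @param unit_costs,wages,vset Costing inputs.
#' @param seed Master seed for imputation and bootstrap streams.
#' @return An object of class `cea_config`.
#' @export
cea_config <- function(data = trial_config(),
                       perspective = c("societal", "healthcare"),
                       approach = c("friction", "human_capital"),
                       outcomes = c("QALY", "BDI", "PFS", "SFS"),
                       outlier_threshold = NULL,
                       outlier_scope = c("all_periods", "offending"),
                       baseline_adjust = FALSE,
                       B = 5000L, m_initial = 5L, m_max = 64L,
                       fmi_threshold = 0.05,
                       lambdas = lambda_grid(),
                       unit_costs = default_unit_costs(),
                       wages = default_wages(),
                       vset = example_value_set(),
                       seed = 1L) {
  if (!inherits(data, "trial_config") && !inherits(data, "trial_data"))
    stopf("`data` must be a trial_config or trial_data object")
  if (!is.null(outlier_threshold))
    assert_number(outlier_threshold, "outlier_threshold", 1e-9)
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  structure(list(
    data = data, perspective = match.arg(perspective),
    approach = match.arg(approach), outcomes = outcomes,
    outlier_threshold = outlier_threshold,
    outlier_scope = match.arg(outlier_scope),
    baseline_adjust = isTRUE(baseline_adjust),
    B = as.integer(B), m_initial = as.integer(m_initial),
    m_max = as.integer(m_max), fmi_threshold = fmi_threshold,
    lambdas = lambdas, unit_costs = unit_costs, wages = wages,
    vset = vset, seed = as.integer(seed)
  ), class = "cea_config")
}

# recode questionnaire-based period costs of cost outliers as missing
.apply_outlier_rule <- function(frame, config) {
  thr <- config$outlier_threshold
  if (is.null(thr)) return(frame)
  periods <- as.integer(sub("^cost_mh_", "",
                            grep("^cost_mh_", names(frame), value = TRUE)))
  soc <- sapply(periods, function(p) {
    cols <- c(paste0("int_", p), paste0("cost_", unname(.cost_stems), "_", p))
    rowSums(as.matrix(frame[cols]))
  })
  flagged <- soc >= thr & !is.na(soc)
  for (j in seq_along(periods)) {
    rows <- if (config$outlier_scope == "all_periods")
      which(rowSums(flagged) > 0) else which(flagged[, j])
    if (length(rows))
      frame[rows, paste0("cost_", unname(.cost_stems), "_", periods[j])] <- NA
  }
  frame
}

#' Run the full trial-based cost-effectiveness analysis
#'
#' Executes the pipeline on all randomised participants (intention to
#' treat): construct outcomes and per-period costs, apply the optional
#' cost-outlier rule, multiply impute missing outcomes and period costs with
#' predictive mean matching (the number of imputations grows until the
#' fraction of missing information of the headline cost and QALY differences
#' is below the threshold), estimate adjusted between-group differences per
#' imputed dataset, bootstrap cost-effect pairs within each imputed dataset,
#' pool by Rubin's rules, and derive ICERs, cost-effectiveness plane
#' quadrant proportions and acceptability curves per outcome. Depression
#' (BDI-II) differences come from the longitudinal model over months 3-12;
#' QALY, PFS and SFS differences from linear models at 12 months; all models
#' adjust for therapy type.
#'
#' @param config A [cea_config()].
#' @return An object of class `cea_report`: list with `effects` (pooled
#'   effect and cost differences with CIs and FMI), `cost_table` (pooled
#'   annual cost-category means per arm), `cea` (per outcome: pooled
#'   differences, ICER with quadrant, quadrant proportions, parametric and
#'   cloud CEACs), `cloud`, `imputation` (m, FMI trace, dropped predictors)
#'   and `meta`.
#' @export
run_cea <- function(config) {
  stopifnot(inherits(config, "cea_config"))
  data <- config$data
  if (inherits(data, "trial_config"))
    data <- inject_missingness(generate_trial(data), data)

  costs <- aggregate_costs(data, config$unit_costs, config$wages,
                           approach = config$approach,
                           perspective = config$perspective)
  frame <- build_analysis_frame(data, costs, config$vset)
  tp <- attr(frame, "timepoints")
  frame <- .apply_outlier_rule(frame, config)

  ## imputation with FMI-adaptive m, monitored on the headline parameters
  spec <- imputation_spec(m_initial = config$m_initial, m_max = config$m_max,
                          fmi_threshold = config$fmi_threshold,
                          seed = config$seed + 100L)
  monitor <- function(d) {
    dc <- adjusted_difference(d, outcome = ".annual_cost",
                              adjusters = c("therapy_ipt",
                                if (config$baseline_adjust) "baseline_cost"))
    d$.qaly <- frame_qaly(d, tp)
    de <- adjusted_difference(d, outcome = ".qaly")
    list(delta_cost = list(estimate = dc$estimate, variance = dc$variance),
         delta_QALY = list(estimate = de$estimate, variance = de$variance))
  }
  monitor_wrap <- function(d) {
    d$.annual_cost <- frame_annual_cost(d, config$perspective)
    monitor(d)
  }
  imp <- adapt_m(frame, spec, monitor_wrap)

  ## per-imputation model-based estimates for the report tables
  cost_adj <- c("therapy_ipt", if (config$baseline_adjust) "baseline_cost")
  per_outcome <- c("cost", config$outcomes)
  model_stats <- lapply(imp$datasets, function(d) {
    d$.annual_cost <- frame_annual_cost(d, config$perspective)
    d$.qaly <- frame_qaly(d, tp)
    res <- list(cost = adjusted_difference(d, ".annual_cost",
                                           adjusters = cost_adj))
    if ("QALY" %in% config$outcomes)
      res$QALY <- adjusted_difference(d, ".qaly")
    if ("PFS" %in% config$outcomes)
      res$PFS <- adjusted_difference(d, paste0("pfs_", max(tp)))
    if ("SFS" %in% config$outcomes)
      res$SFS <- adjusted_difference(d, paste0("sfs_", max(tp)))
    if ("BDI" %in% config$outcomes) {
      fu <- setdiff(tp, 0)
      ld <- data.frame(
        id = rep(d$id, length(fu)), time = rep(fu, each = nrow(d)),
        bdi = unlist(d[paste0("bdi_", fu)], use.names = FALSE),
        twice = rep(d$twice, length(fu)),
        therapy_ipt = rep(d$therapy_ipt, length(fu)),
        baseline = rep(d$bdi_0, length(fu)))
      res$BDI <- longitudinal_effect(ld)
    }
    res
  })
  pooled <- lapply(per_outcome, function(p) {
    est <- vapply(model_stats, function(s) s[[p]]$estimate, numeric(1))
    va <- vapply(model_stats, function(s) s[[p]]$variance, numeric(1))
    rubin_pool(est, va)
  })
  names(pooled) <- per_outcome

  effects <- do.call(rbind, lapply(per_outcome, function(p) {
    q <- pooled[[p]]
    data.frame(outcome = p, estimate = q$estimate, se = q$se,
               ci_lower = q$ci[1], ci_upper = q$ci[2], fmi = q$fmi)
  }))

  ## bootstrap cloud across imputations
  stat <- .make_stat(config, tp)
  cloud <- mi_bootstrap(imp, stat, B = config$B, seed = config$seed + 500L)

  ## decision-analytic outputs per outcome
  dir_of <- c(QALY = 1, PFS = 1, SFS = 1, BDI = -1)
  cea <- lapply(config$outcomes, function(oc) {
    sgn <- dir_of[[oc]]
    cl <- data.frame(delta_cost = cloud$delta_cost,
                     delta_effect = sgn * cloud[[paste0("delta_", oc)]],
                     imputation = cloud$imputation)
    per_imp <- do.call(rbind, lapply(split(cl, cl$imputation), function(s) {
      data.frame(delta_effect = NA, delta_cost = NA,
                 var_effect = stats::var(s$delta_effect),
                 var_cost = stats::var(s$delta_cost),
                 cov_ce = stats::cov(s$delta_effect, s$delta_cost))
    }))
    pi_pts <- attr(cloud, "per_imputation")
    per_imp$delta_effect <- sgn * pi_pts[, paste0("delta_", oc)]
    per_imp$delta_cost <- pi_pts[, "delta_cost"]
    ic <- icer(pooled$cost$estimate, pooled[[oc]]$estimate)
    list(outcome = oc,
         delta_cost = pooled$cost$estimate,
         delta_effect = pooled[[oc]]$estimate,
         icer = ic$icer, icer_quadrant = ic$quadrant,
         quadrants = quadrant_proportions(cl),
         ceac = ceac_parametric(per_imp, config$lambdas),
         ceac_cloud = ceac_cloud(cl, config$lambdas))
  })
  names(cea) <- config$outcomes

  ## pooled annual cost-category table by arm
  stems <- c(intervention = "int", .cost_stems)
  cat_means <- lapply(imp$datasets, function(d) {
    vapply(unname(stems), function(s) {
      cols <- grep(paste0("^", if (s == "int") "int_" else
        paste0("cost_", s, "_")), names(d), value = TRUE)
      tot <- rowSums(as.matrix(d[cols]))
      c(twice = mean(tot[d$twice == 1]), once = mean(tot[d$twice == 0]))
    }, numeric(2))
  })
  cat_mat <- Reduce(`+`, cat_means) / length(cat_means)
  cost_table <- data.frame(category = names(stems),
                           mean_twice = cat_mat["twice", ],
                           mean_once = cat_mat["once", ],
                           row.names = NULL)

  structure(list(
    effects = effects, cost_table = cost_table, cea = cea, cloud = cloud,
    imputation = list(m = imp$m, fmi_trace = attr(imp, "fmi_trace"),
                      dropped_predictors = imp$dropped_predictors),
    meta = list(seed = config$seed, B = config$B,
                perspective = config$perspective,
                approach = config$approach,
                baseline_adjust = config$baseline_adjust,
                outlier_threshold = config$outlier_threshold,
                n = nrow(frame))
  ), class = "cea_report")
}

#' Run one of the four predefined sensitivity analyses
#'
#' Variants differ from the main analysis in exactly one stage:
#' `"healthcare"` restricts the perspective to healthcare costs;
#' `"human_capital"` values paid absenteeism without the friction-period
#' cap; `"outliers"` recodes period costs of participants generating 10 000
#' euro or more societal costs in any follow-up period as missing before
#' imputation; `"baseline_adjust"` adds pre-treatment 3-month societal costs
#' as an adjuster in the cost models.
#'
#' @param config The main-analysis [cea_config()].
#' @param which One of `"healthcare"`, `"human_capital"`, `"outliers"`,
#'   `"baseline_adjust"`.
#' @param outlier_threshold Threshold for the outlier variant.
#' @return A `cea_report`.
#' @export
run_sensitivity <- function(config,
                            which = c("healthcare", "human_capital",
                                      "outliers", "baseline_adjust"),
                            outlier_threshold = 10000) {
  stopifnot(inherits(config, "cea_config"))
  which <- match.arg(which)
  switch(which,
    healthcare = { config$perspective <- "healthcare" },
    human_capital = { config$approach <- "human_capital" },
    outliers = { config$outlier_threshold <- outlier_threshold },
    baseline_adjust = { config$baseline_adjust <- TRUE })
  run_cea(config)
}

#' @export
print.cea_report <- function(x, ...) {
  cat(sprintf("Cost-effectiveness analysis (%s perspective, %s approach, n = %d)\n",
              x$meta$perspective, x$meta$approach, x$meta$n))
  cat(sprintf("  imputations m = %d, bootstrap B = %d per imputation\n",
              x$imputation$m, x$meta$B))
  cat("\nAdjusted differences (twice-weekly minus once-weekly):\n")
  eff <- x$effects
  for (i in seq_len(nrow(eff)))
    cat(sprintf("  %-5s %10.3f  (95%% CI %.3f to %.3f, FMI %.3f)\n",
                eff$outcome[i], eff$estimate[i], eff$ci_lower[i],
                eff$ci_upper[i], eff$fmi[i]))
  cat("\nDecision-analytic results:\n")
  for (oc in names(x$cea)) {
    ce <- x$cea[[oc]]
    cat(sprintf("  %-5s ICER %.0f EUR/unit; quadrants NE %.2f SE %.2f SW %.2f NW %.2f\n",
                oc, ce$icer, ce$quadrants["NE"], ce$quadrants["SE"],
                ce$quadrants["SW"], ce$quadrants["NW"]))
  }
  invisible(x)
}

#' Write a report's tables and curves to disk
#'
#' Writes `report.json` (effects, ICERs, quadrants, metadata),
#' `effects.csv`, `cost_table.csv`, `ceac_<outcome>.csv` and `cloud.csv`
#' into `dir`.
#'
#' @param report A `cea_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cea_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$effects, file.path(dir, "effects.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cost_table, file.path(dir, "cost_table.csv"),
                   row.names = FALSE)
  for (oc in names(report$cea))
    utils::write.csv(as.data.frame(report$cea[[oc]]$ceac),
                     file.path(dir, paste0("ceac_", oc, ".csv")),
                     row.names = FALSE)
  write_cloud(report$cloud, file.path(dir, "cloud.csv"))
  js <- list(
    effects = report$effects,
    cea = lapply(report$cea, function(ce)
      list(delta_cost = ce$delta_cost, delta_effect = ce$delta_effect,
           icer = ce$icer, quadrant = ce$icer_quadrant,
           quadrant_proportions = as.list(ce$quadrants))),
    imputation = list(m = report$imputation$m),
    meta = report$meta
  )
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}
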