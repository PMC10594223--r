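#' Value resource-use counts with a unit-cost table
#'
#' Multiplies each item's quantity by its unit cost and sums within cost
#' categories. Duplicate item entries are summed first, so pre-aggregation
#' does not change the result.
#'
#' @param counts Named numeric vector: item code -> quantity used.
#' @param table A [unit_cost_table()].
#' @return Named numeric vector of costs, one entry per category present in
#'   the table (zero where unused).
#' @export
#' @examples
#' value_resource_use(c(gp_visit = 3, mhc_session = 1), default_unit_costs())
value_resource_use <- function(counts, table) {
  stopifnot(inherits(table, "unit_cost_table"))
  if (any(counts < 0, na.rm = TRUE)) stopf("quantities must be non-negative")
  unknown <- setdiff(names(counts), table$item)
  if (length(unknown))
    stopf("unknown resource-use item(s): %s", paste(unknown, collapse = ", "))
  out <- stats::setNames(numeric(length(unique(table$category))),
                         unique(table$category))
  if (!length(counts)) return(out)
  i <- match(names(counts), table$item)
  cost <- counts * table$unit_cost[i]
  agg <- tapply(cost, table$category[i], sum)
  out[names(agg)] <- agg
  out
}

#' Intervention cost from attended protocol sessions
#'
#' @param sessions_attended Number of protocol psychotherapy sessions
#'   attended (may be fractional as a group mean).
#' @param session_unit_cost Cost per session in euro.
#' @return Cost in euro.
#' @export
intervention_cost <- function(sessions_attended, session_unit_cost) {
  if (any(sessions_attended < 0, na.rm = TRUE))
    stopf("session counts must be non-negative")
  sessions_attended * session_unit_cost
}

#' Presenteeism cost
#'
#' Reduced productivity while attending work with health complaints, valued
#' as `(1 - efficiency) * days with complaints * hours per day * wage`.
#'
#' @param efficiency Self-rated efficiency while working with complaints,
#'   in [0, 1] (1 = fully efficient).
#' @param days_with_complaints Number of working days with health complaints.
#' @param hours_per_day Contracted working hours per day.
#' @param wage Hourly wage in euro.
#' @return Cost in euro.
#' @export
presenteeism_cost <- function(efficiency, days_with_complaints,
                              hours_per_day, wage) {
  if (any(efficiency < 0 | efficiency > 1, na.rm = TRUE))
    stopf("efficiency must lie in [0, 1]")
  if (any(c(days_with_complaints, hours_per_day, wage) < 0, na.rm = TRUE))
    stopf("days, hours and wage must be non-negative")
  (1 - efficiency) * days_with_complaints * hours_per_day * wage
}

#' Absenteeism cost for paid work
#'
#' Values absence episodes at `wage * hours_per_day` per working day. Under
#' the human-capital approach the full episode length is valued; under the
#' friction-cost approach each episode is valued for at most `friction_days`
#' working days, after which a replacement is assumed to restore
#' productivity. The cap applies per episode, however many questionnaire
#' periods the episode spans.
#'
#' @param episode_days Numeric vector of episode lengths in working days.
#' @param wage Hourly wage in euro.
#' @param hours_per_day Contracted working hours per day.
#' @param approach `"friction"` or `"human_capital"`.
#' @param friction_days Friction period in working days (default 60 = 12
#'   weeks at 5 days/week).
#' @return Total cost in euro over all episodes.
#' @export
#' @examples
#' absenteeism_cost(100, wage = 40, hours_per_day = 8,
#'                  approach = "friction", friction_days = 60)     # 19200
#' absenteeism_cost(100, wage = 40, hours_per_day = 8,
#'                  approach = "human_capital")                    # 32000
absenteeism_cost <- function(episode_days, wage, hours_per_day,
                             approach = c("friction", "human_capital"),
                             friction_days = 60) {
  approach <- match.arg(approach)
  if (any(episode_days < 0, na.rm = TRUE))
    stopf("episode lengths must be non-negative")
  valued <- if (approach == "friction") pmin(episode_days, friction_days)
            else episode_days
  sum(valued * wage * hours_per_day)
}

#' Cost of lost unpaid work
#'
#' Hours of unpaid work (housekeeping, care tasks) that others had to take
#' over, valued at the shadow price of a legally employed cleaner.
#'
#' @param hours_lost Hours of unpaid work lost.
#' @param shadow_price Shadow price per hour in euro.
#' @return Cost in euro.
#' @export
unpaid_work_cost <- function(hours_lost, shadow_price) {
  if (any(c(hours_lost, shadow_price) < 0, na.rm = TRUE))
    stopf("hours and shadow price must be non-negative")
  hours_lost * shadow_price
}

# column -> unit-cost item mapping for the generator's long format
.count_items <- c(gp_visits = "gp_visit", mhc_sessions = "mhc_session",
                  admission_days = "psych_admission_day", med_days = "med_dd",
                  informal_hours = "informal_hour")

#' Aggregate a trial dataset into per-participant per-period costs
#'
#' Produces a cost breakdown per participant per 3-month period (period 0 is
#' the 3 months before start of treatment, periods 1-4 the follow-up
#' quarters ending at months 3, 6, 9 and 12): healthcare categories from the
#' valued resource-use counts, intervention cost from attended sessions
#' (attributed evenly over periods 1-2, the treatment phase), absenteeism
#' from paid work per episode (friction or human-capital), presenteeism,
#' lost unpaid work, and informal care. Costs whose source data are missing
#' at a timepoint are `NA` (to be multiply imputed); participants not in
#' paid employment have structurally zero paid-productivity costs.
#'
#' Absence episodes are valued per episode and the valued days attributed to
#' consecutive periods from the onset period at `wages$workdays_per_period`
#' working days per period (days beyond the last follow-up period are kept in
#' period 4, so no valued day is lost).
#'
#' @param data A `trial_data` object.
#' @param table A [unit_cost_table()]; must resolve every count column.
#' @param wages A [wage_schedule()].
#' @param approach `"friction"` (default) or `"human_capital"` for paid
#'   absenteeism.
#' @param perspective `"societal"` (default) or `"healthcare"`; selects which
#'   components enter the `total` column. All components are retained either
#'   way.
#' @return An object of class `cost_breakdown`: list with `periods` (one row
#'   per participant-period, component and total columns) and `annual` (one
#'   row per participant: follow-up totals over periods 1-4 and
#'   `baseline_cost`, the period-0 societal total).
#' @export
aggregate_costs <- function(data, table = default_unit_costs(),
                            wages = default_wages(),
                            approach = c("friction", "human_capital"),
                            perspective = c("societal", "healthcare")) {
  stopifnot(inherits(data, "trial_data"), inherits(table, "unit_cost_table"),
            inherits(wages, "wage_schedule"))
  approach <- match.arg(approach)
  perspective <- match.arg(perspective)
  long <- data$long
  b <- data$baseline
  tp <- sort(unique(long$time_m))
  n_periods <- length(tp) - 1L

  cols <- intersect(names(.count_items), names(long))
  price <- stats::setNames(table$unit_cost, table$item)
  cat_of <- stats::setNames(table$category, table$item)
  missing_items <- setdiff(.count_items[cols], table$item)
  if (length(missing_items))
    stopf("unit-cost table does not resolve item(s): %s",
          paste(missing_items, collapse = ", "))

  out <- data.frame(id = long$id, period = match(long$time_m, tp) - 1L)
  for (cc in c("mental_healthcare", "other_healthcare", "medication",
               "informal_care"))
    out[[cc]] <- 0
  for (cl in cols) {
    item <- .count_items[[cl]]
    out[[cat_of[[item]]]] <- out[[cat_of[[item]]]] + long[[cl]] * price[[item]]
  }

  # intervention: attended protocol sessions, treatment phase = periods 1-2
  sess_cost <- intervention_cost(b$sessions_attended,
                                 price[["psychotherapy_session"]])
  out$intervention <- ifelse(out$period %in% c(1L, 2L),
                             sess_cost[match(out$id, b$id)] / 2, 0)

  # productivity
  wage <- wages$wages[ifelse(b$female[match(out$id, b$id)] == 1,
                             "female", "male")]
  hpd <- b$hours_day[match(out$id, b$id)]
  emp <- b$employed[match(out$id, b$id)] == 1
  out$presenteeism <- ifelse(emp,
    presenteeism_cost(long$efficiency, long$complaint_days, hpd, wage), 0)
  out$absenteeism_unpaid <- unpaid_work_cost(long$unpaid_hours,
                                             wages$shadow_price)
  out$absenteeism_paid <- ifelse(emp, 0, 0)  # numeric, NA-filled below
  # period unobserved -> paid absence unknown for employed participants
  out$absenteeism_paid[emp & !long$observed] <- NA

  if (nrow(data$episodes)) {
    ep <- data$episodes
    valued <- if (approach == "friction")
      pmin(ep$working_days, wages$friction_days) else ep$working_days
    ewage <- wages$wages[ifelse(b$female[match(ep$id, b$id)] == 1,
                                "female", "male")]
    ehpd <- b$hours_day[match(ep$id, b$id)]
    wpp <- wages$workdays_per_period
    for (e in seq_len(nrow(ep))) {
      left <- valued[e]
      p <- ep$onset_period[e]
      while (left > 0) {
        share <- if (p >= n_periods) left else min(left, wpp)
        r <- which(out$id == ep$id[e] & out$period == p)
        if (length(r) && !is.na(out$absenteeism_paid[r]))
          out$absenteeism_paid[r] <- out$absenteeism_paid[r] +
            share * ewage[e] * ehpd[e]
        left <- left - share
        p <- min(p + 1L, n_periods)
      }
    }
  }

  hc_cats <- c("intervention", "mental_healthcare", "other_healthcare",
               "medication")
  out$healthcare_total <- rowSums(out[hc_cats])
  out$lost_productivity_total <- out$absenteeism_paid + out$absenteeism_unpaid +
    out$presenteeism
  out$societal_total <- out$healthcare_total + out$informal_care +
    out$lost_productivity_total
  out$total <- if (perspective == "societal") out$societal_total
               else out$healthcare_total

  fu <- out$period > 0
  annual <- stats::aggregate(
    out[fu, c(hc_cats, "informal_care", "absenteeism_paid",
              "absenteeism_unpaid", "presenteeism", "healthcare_total",
              "lost_productivity_total", "societal_total", "total")],
    by = list(id = out$id[fu]), FUN = sum)
  annual$baseline_cost <- out$societal_total[out$period == 0][
    match(annual$id, out$id[out$period == 0])]

  structure(list(periods = out, annual = annual),
            class = "cost_breakdown",
            approach = approach, perspective = perspective)
}

#' Write a per-participant cost breakdown to CSV
#'
#' @param costs A `cost_breakdown` from [aggregate_costs()].
#' @param path Output CSV path (per participant-period rows).
#' @export
write_cost_breakdown <- function(costs, path) {
  stopifnot(inherits(costs, "cost_breakdown"))
  utils::write.csv(costs$periods, path, row.names = FALSE, na = "")
  invisible(path)
}
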