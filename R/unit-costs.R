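#' Unit-cost tables and wage schedules
#'
#' Resource-use items are valued with a unit-cost table: one row per item
#' with its unit of measurement, a cost category and the cost per unit in
#' euro (price index year configurable, 2021 by default). Categories are
#' `intervention`, `mental_healthcare`, `other_healthcare`, `medication` and
#' `informal_care`; the first four constitute the healthcare perspective,
#' all five plus lost productivity the societal perspective.
#'
#' @param items Data frame with columns `item`, `description`, `category`,
#'   `unit`, `unit_cost`.
#' @param index_year Price index year of the costs.
#' @return An object of class `unit_cost_table` (a data frame).
#' @export
unit_cost_table <- function(items, index_year = 2021) {
  need <- c("item", "description", "category", "unit", "unit_cost")
  if (!all(need %in% names(items)))
    stopf("unit-cost table needs columns: %s", paste(need, collapse = ", "))
  ok <- c("intervention", "mental_healthcare", "other_healthcare",
          "medication", "informal_care")
  bad <- setdiff(items$category, ok)
  if (length(bad)) stopf("unknown cost category: %s", paste(bad, collapse = ", "))
  if (any(items$unit_cost < 0)) stopf("unit costs must be non-negative")
  if (anyDuplicated(items$item)) stopf("duplicate item codes")
  structure(as.data.frame(items), class = c("unit_cost_table", "data.frame"),
            index_year = index_year)
}

#' @rdname unit_cost_table
#' @details `default_unit_costs()` returns the package's illustrative table
#'   used by the synthetic generator and the examples. Prices are plausible
#'   round numbers, not reproductions of any national standard-cost list.
#' @export
default_unit_costs <- function() {
  unit_cost_table(data.frame(
    item = c("psychotherapy_session", "gp_visit", "mhc_session",
             "psych_admission_day", "med_dd", "informal_hour"),
    description = c("protocol CBT/IPT session (45 min)",
                    "general practitioner consultation",
                    "other mental healthcare contact",
                    "psychiatric hospital admission day",
                    "antidepressant, defined daily dose",
                    "informal care provided by family/friends"),
    category = c("intervention", "other_healthcare", "mental_healthcare",
                 "mental_healthcare", "medication", "informal_care"),
    unit = c("session", "visit", "contact", "day", "DDD", "hour"),
    unit_cost = c(100, 33, 100, 300, 0.25, 16),
    stringsAsFactors = FALSE
  ))
}

#' @rdname unit_cost_table
#' @param path CSV file with the unit-cost table columns.
#' @export
read_unit_costs <- function(path, index_year = 2021) {
  unit_cost_table(utils::read.csv(path, stringsAsFactors = FALSE),
                  index_year = index_year)
}

#' Wage schedule for valuing lost productivity
#'
#' Holds gender-specific gross hourly wage rates for valuing absenteeism and
#' presenteeism, the shadow price of unpaid work (the hourly rate of a
#' legally employed cleaner) and the friction period in working days: under
#' the friction-cost approach an absent worker is assumed replaced after the
#' friction period, so each absence episode is valued for at most that many
#' working days.
#'
#' @param wages Named numeric vector of hourly wages, names `male`, `female`.
#' @param shadow_price Hourly shadow price for unpaid work.
#' @param friction_days Friction period in working days (12 weeks at a
#'   5-day working week = 60 by default).
#' @param workdays_per_period Working days in one 3-month costing period,
#'   used to attribute multi-period absence episodes.
#' @return An object of class `wage_schedule`.
#' @export
wage_schedule <- function(wages = c(male = 41, female = 36),
                          shadow_price = 16,
                          friction_days = 60,
                          workdays_per_period = 65) {
  if (any(wages <= 0)) stopf("wages must be positive")
  assert_number(shadow_price, "shadow_price", 0)
  assert_number(friction_days, "friction_days", 1)
  structure(list(wages = wages, shadow_price = shadow_price,
                 friction_days = friction_days,
                 workdays_per_period = workdays_per_period),
            class = "wage_schedule")
}

#' @rdname wage_schedule
#' @export
default_wages <- function() wage_schedule()

#' @rdname wage_schedule
#' @param path YAML file with fields `wages` (mapping gender to hourly
#'   wage), `shadow_price`, `friction_days` and optionally
#'   `workdays_per_period`.
#' @export
read_wage_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  wage_schedule(wages = unlist(y$wages),
                shadow_price = y$shadow_price,
                friction_days = y$friction_days,
                workdays_per_period = y$workdays_per_period %||% 65)
}
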