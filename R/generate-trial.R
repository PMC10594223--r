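#' Generate a fully observed synthetic trial dataset
#'
#' Simulates participant-level longitudinal data with the statistical
#' structure the downstream economic evaluation assumes: baseline BDI-II of
#' at least 20, block randomisation (block size 4) stratified by depression
#' severity (BDI-II >= 29) and site with exactly the requested cell sizes,
#' BDI-II trajectories equal to the configured group means plus a participant
#' random effect and residual noise, utilities negatively correlated with
#' concurrent depression severity, heavy-tailed (log-scale and overdispersed
#' count) resource use with occasional very high mental-healthcare outliers,
#' absence episodes some of which exceed the friction period, and attended
#' session counts near 16.5 / 14.7 truncated to [0, 20].
#'
#' The mental-healthcare contact intensity in the twice-weekly arm is
#' calibrated so that, valued with [default_unit_costs()], the expected annual
#' societal cost difference between arms equals `config$true_cost_diff`
#' (inclusive of the intervention-cost difference implied by the session
#' schedules).
#'
#' @param config A [trial_config()].
#' @return An object of class `trial_data`: a list with elements
#'   \describe{
#'     \item{baseline}{one row per participant: id, arms, site, severity
#'       stratum, covariates and attended sessions;}
#'     \item{long}{one row per participant-timepoint: clinical outcomes,
#'       resource-use counts for the preceding 3-month period, presenteeism
#'       inputs and an `observed` flag (all `TRUE` here);}
#'     \item{episodes}{paid-work absence episodes: id, onset period and
#'       length in working days.}
#'   }
#' @export
#' @examples
#' d <- generate_trial(trial_config(seed = 42))
#' table(d$baseline$frequency_arm)
generate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  tp <- config$timepoints
  k <- length(tp)
  n <- sum(config$cell_sizes)
  cells <- c("twice_cbt", "once_cbt", "twice_ipt", "once_ipt")
  quota <- stats::setNames(config$cell_sizes, cells)

  ## --- baseline covariates ------------------------------------------------
  site <- sample.int(config$n_sites, n, replace = TRUE)
  age <- round(rtnorm(n, 38, 12, 18, 64))
  female <- stats::rbinom(n, 1, 0.65)
  education <- sample(1:3, n, replace = TRUE, prob = c(0.25, 0.40, 0.35))
  employed <- stats::rbinom(n, 1, 0.60)
  hours_day <- ifelse(employed == 1,
                      sample(c(4, 6, 8), n, replace = TRUE,
                             prob = c(0.2, 0.3, 0.5)), 0)
  bdi_0 <- round(rtnorm(n, 31, 8, 20, 63))
  severity <- ifelse(bdi_0 >= 29, "high", "low")

  ## --- stratified block randomisation (exact cell totals) -----------------
  # participants enter in a global random order (so leftover-quota drift is
  # independent of covariates); each severity-by-site stratum keeps its own
  # running block of 4 within which all four cells are preferred once
  cell <- character(n)
  blocks <- new.env(parent = emptyenv())
  for (i in sample.int(n)) {
    key <- paste(severity[i], site[i])
    in_block <- if (is.null(blocks[[key]])) character(0) else blocks[[key]]
    open <- names(quota)[quota > 0]
    prefer <- setdiff(open, in_block)    # balance within blocks of 4
    pool <- if (length(prefer)) prefer else open
    pick <- if (length(pool) == 1L) pool else
      sample(pool, 1L, prob = quota[pool])
    cell[i] <- pick
    quota[pick] <- quota[pick] - 1L
    in_block <- c(in_block, pick)
    blocks[[key]] <- if (length(in_block) == 4L) character(0) else in_block
  }
  twice <- as.integer(cell %in% c("twice_cbt", "twice_ipt"))
  therapy <- ifelse(cell %in% c("twice_cbt", "once_cbt"), "CBT", "IPT")

  sessions <- clip(stats::rnorm(n, config$sessions_mean[
    ifelse(twice == 1, "twice", "once")], 2), 0, 20)
  outlier <- stats::rbinom(n, 1, config$outlier_rate)

  baseline <- data.frame(
    id = seq_len(n),
    frequency_arm = ifelse(twice == 1, "twice", "once"),
    therapy = therapy, site = site,
    severity_stratum = severity,
    age = age, female = female, education = education,
    employed = employed, hours_day = hours_day,
    bdi_baseline = bdi_0,
    sessions_attended = sessions,
    stringsAsFactors = FALSE
  )

  ## --- longitudinal outcomes ----------------------------------------------
  # Common course of the cohort: marked improvement to month 6, then plateau.
  course <- stats::approx(c(0, 3, 6, 9, 12), c(0, -8, -11, -12, -12.5),
                          xout = tp)$y
  b_i <- stats::rnorm(n, 0, 4)          # participant-level random effect
  u_i <- stats::rnorm(n, 0, 0.04)

  long <- expand.grid(id = seq_len(n), time_m = tp, KEEP.OUT.ATTRS = FALSE)
  long <- long[order(long$id, long$time_m), , drop = FALSE]
  rownames(long) <- NULL
  ix <- long$id
  ti <- match(long$time_m, tp)
  follow <- as.integer(long$time_m > 0)

  bdi_base <- bdi_0[ix] + course[ti] +
    follow * (b_i[ix] + stats::rnorm(nrow(long), 0, 4.5))
  long$bdi <- round(clip(bdi_base + twice[ix] * config$true_effect_bdi[ti],
                         0, 63))

  vs <- example_value_set()
  if (config$generate_states) {
    long$eq5d5l_state <- .states_from_severity(bdi_base)
    long$utility <- utility_from_state(long$eq5d5l_state, vs) +
      twice[ix] * config$true_effect_utility[ti]
    long$utility <- clip(long$utility, vs$minimum, 1)
  } else {
    long$eq5d5l_state <- NA_character_
    long$utility <- clip(
      0.90 - 0.010 * bdi_base + u_i[ix] +
        follow * stats::rnorm(nrow(long), 0, 0.05) +
        twice[ix] * config$true_effect_utility[ti],
      vs$minimum, 1)
  }
  long$pfs <- clip(80 - 0.6 * bdi_base + stats::rnorm(n, 0, 6)[ix] +
                     stats::rnorm(nrow(long), 0, 7), 0, 100)
  long$sfs <- clip(95 - 1.2 * bdi_base + stats::rnorm(nrow(long), 0, 9),
                   0, 100)

  ## --- resource use (counts over the preceding 3 months) ------------------
  uc <- default_unit_costs()
  price <- stats::setNames(uc$unit_cost, uc$item)
  n_follow <- k - 1L
  sess_diff <- clipped_normal_mean(config$sessions_mean[["twice"]], 2, 0, 20) -
    clipped_normal_mean(config$sessions_mean[["once"]], 2, 0, 20)
  extra_mhc <- (config$true_cost_diff -
                  sess_diff * price[["psychotherapy_session"]]) /
    (n_follow * price[["mhc_session"]])

  # resource use driven by the arm-effect-free severity process, so the
  # configured cost difference flows only through its designated channels
  mu_gp <- pmax(0.6 + 0.03 * bdi_base, 0.01)
  mu_mhc <- pmax(0.4 + 0.05 * bdi_base + follow * twice[ix] * extra_mhc,
                 0.01)
  long$gp_visits <- stats::rnbinom(nrow(long), mu = mu_gp, size = 1.2)
  long$mhc_sessions <- stats::rnbinom(nrow(long), mu = mu_mhc, size = 1.5)
  long$med_days <- pmin(stats::rnbinom(nrow(long), mu = 30, size = 0.5), 92)
  long$informal_hours <- round(stats::rbinom(nrow(long), 1, 0.25) *
                                 stats::rlnorm(nrow(long), log(20), 0.7), 1)

  # mental-healthcare outliers, e.g. psychiatric admission, in one random
  # follow-up period of flagged participants
  long$admission_days <- 0
  if (any(outlier == 1) && n_follow > 0) {
    for (i in which(outlier == 1)) {
      p <- sample(tp[-1], 1L)
      r <- long$id == i & long$time_m == p
      long$admission_days[r] <- 5 + stats::rpois(1, 15)
    }
  }

  ## --- productivity inputs -------------------------------------------------
  emp <- employed[ix] == 1
  long$complaint_days <- ifelse(emp, stats::rpois(nrow(long),
                                                  pmax(0.2 * bdi_base, 0)), 0)
  long$efficiency <- clip(1 - 0.012 * bdi_base -
                            abs(stats::rnorm(nrow(long), 0, 0.06)), 0, 1)
  long$unpaid_hours <- round(stats::rbinom(nrow(long), 1, 0.35) *
                               stats::rlnorm(nrow(long), log(10), 0.8), 1)
  long$observed <- TRUE

  # absence episodes: onset probability rises with concurrent severity;
  # lognormal working-day lengths, a tail beyond the 60-day friction period
  ep_row <- emp & stats::runif(nrow(long)) <
    stats::plogis(-2.5 + 0.05 * bdi_base)
  ne <- sum(ep_row)
  episodes <- data.frame(
    id = long$id[ep_row],
    episode = seq_len(ne),
    onset_period = match(long$time_m[ep_row], tp) - 1L,  # 0 = pre-treatment
    working_days = pmin(ceiling(stats::rlnorm(ne, 2.2, 1.2)), 190)
  )

  structure(list(baseline = baseline, long = long, episodes = episodes),
            class = "trial_data", config = config)
}

# Map latent severity to plausible EQ-5D-5L profiles: higher depression makes
# worse levels in every dimension more likely, most strongly anxiety/depression.
.states_from_severity <- function(bdi) {
  sev <- clip(bdi / 63, 0, 1)
  load <- c(0.25, 0.15, 0.5, 0.45, 0.9)  # MO SC UA PD AD
  m <- vapply(load, function(w) {
    1L + stats::rbinom(length(sev), 4L, clip(w * sev, 0, 0.95))
  }, integer(length(sev)))
  apply(m, 1L, paste0, collapse = "")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Synthetic trial data: %d participants, %d assessments, %d absence episodes\n",
              nrow(x$baseline), nrow(x$long), nrow(x$episodes)))
  obs <- tapply(x$long$observed, x$long$time_m, mean)
  cat("  followed up:",
      paste(sprintf("%s m: %.0f%%", names(obs), 100 * obs), collapse = ", "),
      "\n")
  invisible(x)
}

#' Impose missing-at-random dropout on a fully observed trial dataset
#'
#' Sets follow-up assessments to missing so that the expected fraction
#' followed up at each timepoint matches `config$dropout_targets`. The
#' probability of remaining in follow-up increases with education and
#' baseline physical functioning (and with nothing else), so the mechanism is
#' missing at random given fully observed baseline covariates; completers are
#' more highly educated and have higher physical functioning, as observed in
#' the trial. A whole assessment is missed at once; in addition 2% of
#' individual items among retained assessments are blanked. Baseline remains
#' complete.
#'
#' @param data A `trial_data` object (fully observed).
#' @param config The [trial_config()] used to generate it.
#' @return The dataset with `observed` flags and `NA`s set.
#' @export
inject_missingness <- function(data, config) {
  stopifnot(inherits(data, "trial_data"), inherits(config, "trial_config"))
  if (any(config$dropout_targets < 0 | config$dropout_targets > 1))
    stopf("dropout targets must lie in [0, 1]")
  set.seed(config$seed + 1L)
  tp <- config$timepoints
  b <- data$baseline
  # MAR linear predictor (education and baseline physical functioning only)
  pfs0 <- data$long$pfs[match(paste(b$id, 0),
                              paste(data$long$id, data$long$time_m))]
  z <- 0.5 * (b$education - mean(b$education)) + 0.03 * (pfs0 - mean(pfs0))

  item_cols <- c("bdi", "utility", "pfs", "sfs", "gp_visits", "mhc_sessions",
                 "med_days", "informal_hours", "admission_days",
                 "complaint_days", "efficiency", "unpaid_hours")
  for (j in seq_along(tp)[-1]) {
    f <- config$dropout_targets[j]
    if (f >= 1) next
    alpha <- stats::uniroot(function(a) mean(stats::plogis(a + z)) - f,
                            c(-20, 20))$root
    miss <- stats::runif(nrow(b)) >= stats::plogis(alpha + z)
    rows <- data$long$time_m == tp[j] & data$long$id %in% b$id[miss]
    data$long$observed[rows] <- FALSE
    data$long[rows, item_cols] <- NA
    if (!is.na(match("eq5d5l_state", names(data$long))))
      data$long$eq5d5l_state[rows] <- NA
  }
  # sporadic item-level gaps among retained follow-up assessments
  ret <- which(data$long$observed & data$long$time_m > 0)
  for (cl in item_cols) {
    gap <- ret[stats::runif(length(ret)) < 0.02]
    data$long[gap, cl] <- NA
  }
  data
}

#' Write / read a trial dataset as delimited text
#'
#' Long format (one row per participant-timepoint), a participant-level
#' baseline table and an absence-episode table, as three CSV files with
#' missing values encoded as empty fields.
#'
#' @param data A `trial_data` object.
#' @param dir Directory to write into (created if needed).
#' @return `write_trial_csv` returns the directory invisibly;
#'   `read_trial_csv` returns a `trial_data` object.
#' @export
write_trial_csv <- function(data, dir) {
  stopifnot(inherits(data, "trial_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data$baseline, file.path(dir, "baseline.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(data$long, file.path(dir, "long.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(data$episodes, file.path(dir, "episodes.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), na.strings = "",
                                    stringsAsFactors = FALSE)
  long <- rd("long.csv")
  long$observed <- as.logical(long$observed)
  if (!"eq5d5l_state" %in% names(long)) long$eq5d5l_state <- NA_character_
  structure(list(baseline = rd("baseline.csv"), long = long,
                 episodes = rd("episodes.csv")),
            class = "trial_data")
}
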