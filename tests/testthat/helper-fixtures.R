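# Shared fixtures built in code.

# small trial for fast structural tests
small_config <- function(seed = 1, ...) {
  trial_config(cell_sizes = c(15L, 15L, 15L, 15L), n_sites = 3L, seed = seed,
               ...)
}

# a trial_data object with a single participant and hand-set values
one_participant_data <- function(sessions = 16, employed = 0) {
  baseline <- data.frame(
    id = 1L, frequency_arm = "twice", therapy = "CBT", site = 1L,
    severity_stratum = "high", age = 40, female = 1, education = 2,
    employed = employed, hours_day = if (employed) 8 else 0,
    bdi_baseline = 30, sessions_attended = sessions)
  long <- data.frame(
    id = 1L, time_m = c(0, 3, 6, 9, 12), bdi = 30,
    eq5d5l_state = NA_character_, utility = 0.7, pfs = 60, sfs = 60,
    gp_visits = 0, mhc_sessions = 0, med_days = 0, informal_hours = 0,
    admission_days = 0, complaint_days = 0, efficiency = 1,
    unpaid_hours = 0, observed = TRUE)
  episodes <- data.frame(id = integer(), episode = integer(),
                         onset_period = integer(), working_days = numeric())
  structure(list(baseline = baseline, long = long, episodes = episodes),
            class = "trial_data")
}

# brute-force BCa endpoints from the full resample distribution, written
# directly from the textbook definitions (independent of the package path)
enumerate_bca <- function(x, statistic, conf = 0.95) {
  n <- length(x)
  idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  reps <- apply(idx, 1L, function(i) statistic(x[i]))
  t0 <- statistic(x)
  z0 <- qnorm(mean(reps < t0) + 0.5 * mean(reps == t0))
  jack <- vapply(seq_len(n), function(i) statistic(x[-i]), numeric(1))
  dj <- mean(jack) - jack
  a <- sum(dj^3) / (6 * sum(dj^2)^1.5)
  al <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  zq <- qnorm(al)
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  list(t0 = t0, ci = unname(quantile(reps, adj, type = 7)), reps = reps,
       z0 = z0, a = a, adj = adj)
}
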