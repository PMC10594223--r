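test_that("requested cell sizes are produced exactly and arms add up", {
  d <- generate_trial(trial_config(seed = 2))
  tab <- table(d$baseline$frequency_arm, d$baseline$therapy)
  expect_equal(unname(tab["twice", "CBT"]), 49)
  expect_equal(unname(tab["once", "CBT"]), 49)
  expect_equal(unname(tab["twice", "IPT"]), 47)
  expect_equal(unname(tab["once", "IPT"]), 55)
  expect_equal(nrow(d$baseline), 200)
  expect_equal(sum(d$baseline$frequency_arm == "twice"), 96)
  expect_equal(sum(d$baseline$frequency_arm == "once"), 104)
})

test_that("the generator is deterministic in config + seed", {
  a <- generate_trial(trial_config(seed = 9))
  b <- generate_trial(trial_config(seed = 9))
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$long, b$long)
  expect_identical(a$episodes, b$episodes)
  cfg <- trial_config(seed = 9)
  expect_identical(inject_missingness(a, cfg), inject_missingness(b, cfg))
})

test_that("generated values respect their scales", {
  d <- generate_trial(trial_config(seed = 5))
  expect_true(all(d$baseline$bdi_baseline >= 20))
  expect_true(all(d$long$bdi >= 0 & d$long$bdi <= 63))
  expect_true(all(d$long$pfs >= 0 & d$long$pfs <= 100))
  expect_true(all(d$long$sfs >= 0 & d$long$sfs <= 100))
  expect_true(all(d$long$efficiency >= 0 & d$long$efficiency <= 1))
  vs <- example_value_set()
  expect_true(all(d$long$utility <= 1 & d$long$utility >= vs$minimum))
  expect_true(all(d$baseline$sessions_attended >= 0 &
                    d$baseline$sessions_attended <= 20))
  expect_true(all((d$baseline$severity_stratum == "high") ==
                    (d$baseline$bdi_baseline >= 29)))
})

test_that("utilities are negatively correlated with concurrent depression", {
  d <- generate_trial(trial_config(seed = 6))
  expect_lt(cor(d$long$bdi, d$long$utility), -0.5)
})

test_that("null configuration produces null arm differences", {
  cfg <- trial_config(true_effect_bdi = rep(0, 5),
                      true_effect_utility = rep(0, 5),
                      true_cost_diff = 0, outlier_rate = 0)
  diffs <- vapply(1:25, function(s) {
    cfg$seed <- s
    d <- generate_trial(cfg)
    tw <- d$baseline$frequency_arm == "twice"
    a <- aggregate_costs(d)$annual
    c(bdi = mean(d$long$bdi[d$long$id %in% d$baseline$id[tw]]) -
        mean(d$long$bdi[d$long$id %in% d$baseline$id[!tw]]),
      cost = mean(a$societal_total[match(d$baseline$id[tw], a$id)]) -
        mean(a$societal_total[match(d$baseline$id[!tw], a$id)]))
  }, numeric(2))
  expect_lt(abs(mean(diffs["bdi", ])), 3 * sd(diffs["bdi", ]) / 5)
  expect_lt(abs(mean(diffs["cost", ])), 3 * sd(diffs["cost", ]) / 5)
})

test_that("dropout reproduces the target follow-up counts", {
  cfg <- trial_config(seed = 31)
  counts <- matrix(0, 20, 5)
  for (s in 1:20) {
    cfg$seed <- s + 300
    d <- inject_missingness(generate_trial(cfg), cfg)
    counts[s, ] <- tapply(d$long$observed, d$long$time_m, sum)
  }
  target <- c(200, 145, 153, 140, 138)
  # mean observed counts within 3 SE of the binomial expectation
  se <- sqrt(target * (1 - target / 200)) / sqrt(20)
  expect_true(all(abs(colMeans(counts) - target) < pmax(3 * se, 1)))
  # baseline always complete
  expect_equal(counts[, 1], rep(200, 20))
})

test_that("dropout_targets of 1 leave the dataset unchanged", {
  cfg <- trial_config(dropout_targets = rep(1, 5), seed = 4)
  d <- generate_trial(cfg)
  dm <- inject_missingness(d, cfg)
  # whole-assessment dropout is off; only the 2% item-level gaps remain
  expect_true(all(dm$long$observed))
  expect_gt(mean(!is.na(dm$long$bdi)), 0.97)
})

test_that("missingness is MAR: completers differ on education and PFS, not on the unseen outcome", {
  cfg <- trial_config(seed = 18)
  d0 <- generate_trial(cfg)
  d <- inject_missingness(d0, cfg)
  obs12 <- d$long$observed[d$long$time_m == 12]
  edu <- d$baseline$education
  expect_gt(mean(edu[obs12]), mean(edu[!obs12]))
  # regression of the missingness indicator on the held-out true outcome,
  # given the MAR covariates, shows no residual dependence (pooled trials)
  zs <- vapply(1:15, function(s) {
    cfg$seed <- s + 70
    full <- generate_trial(cfg)
    masked <- inject_missingness(full, cfg)
    r <- masked$long$time_m == 12
    pfs0 <- full$long$pfs[full$long$time_m == 0]
    fit <- suppressWarnings(glm(
      masked$long$observed[r] ~ full$long$bdi[r] +
        full$baseline$education + pfs0, family = binomial))
    summary(fit)$coefficients[2, "z value"]
  }, numeric(1))
  expect_lt(abs(mean(zs)), 3 / sqrt(15))
})

test_that("CSV round trip preserves the dataset", {
  cfg <- small_config(seed = 12)
  d <- inject_missingness(generate_trial(cfg), cfg)
  dir <- withr::local_tempdir()
  write_trial_csv(d, dir)
  d2 <- read_trial_csv(dir)
  expect_equal(d2$baseline, d$baseline)
  expect_equal(d2$episodes, d$episodes)
  expect_equal(d2$long$bdi, d$long$bdi)
  expect_equal(d2$long$observed, d$long$observed)
  expect_equal(d2$long$utility, d$long$utility, tolerance = 1e-12)
})

test_that("invalid configurations are rejected", {
  expect_error(trial_config(timepoints = c(0, 3, 3, 9, 12)), "increasing")
  expect_error(trial_config(dropout_targets = c(1, 1.2, 1, 1, 1)), "0, 1")
  expect_error(trial_config(cell_sizes = c(0, 0, 0, 0)), "positive")
  expect_error(trial_config(true_effect_bdi = c(0, 1)), "per timepoint")
})

test_that("state-profile generation feeds utilities through the value set", {
  cfg <- small_config(seed = 3, generate_states = TRUE)
  d <- generate_trial(cfg)
  expect_true(all(grepl("^[1-5]{5}$", d$long$eq5d5l_state)))
  vs <- example_value_set()
  base <- d$long$time_m == 0  # no arm effect at baseline
  expect_equal(d$long$utility[base],
               utility_from_state(d$long$eq5d5l_state[base], vs))
})

test_that("trial configurations round-trip through YAML", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "trial.yaml")
  writeLines(c("seed: 12", "true_cost_diff: 1500",
               "cell_sizes: [10, 10, 10, 10]", "n_sites: 2"), p)
  cfg <- read_trial_config(p)
  expect_equal(cfg$seed, 12L)
  expect_equal(cfg$true_cost_diff, 1500)
  expect_equal(sum(cfg$cell_sizes), 40)
  expect_identical(generate_trial(cfg),
                   generate_trial(trial_config(cell_sizes = rep(10L, 4),
                                               n_sites = 2, seed = 12,
                                               true_cost_diff = 1500)))
  writeLines("true_cost_diff: 1500", p)
  expect_error(read_trial_config(p), "seed")
})
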