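test_that("adjusted difference recovers a built-in effect and respects orthogonal adjusters", {
  set.seed(4)
  n <- 4000
  d <- data.frame(twice = rep(0:1, n / 2),
                  therapy_ipt = rep(c(0, 1), each = n / 2))
  d$y <- 2 + 1.5 * d$twice + 0.5 * d$therapy_ipt + rnorm(n)
  e <- adjusted_difference(d, "y")
  expect_equal(e$estimate, 1.5, tolerance = 0.1)
  expect_true(e$ci[1] < e$estimate & e$estimate < e$ci[2])
  # a balanced adjuster orthogonal to the arm leaves the estimate unchanged
  d$z <- rep(c(-1, 1), n / 2)[sample.int(n)]
  d$z <- d$z - mean(d$z)
  e2 <- adjusted_difference(d, "y", adjusters = c("therapy_ipt"))
  e3 <- adjusted_difference(d, "y", adjusters = c("therapy_ipt", "z"))
  expect_equal(e3$estimate, e2$estimate, tolerance = 0.02)
})

test_that("constant outcomes and degenerate designs are handled", {
  d <- data.frame(twice = rep(0:1, 10), therapy_ipt = rep(c(0, 0, 1, 1), 5),
                  y = 5)
  e <- suppressWarnings(adjusted_difference(d, "y"))  # lm's perfect-fit note
  expect_equal(e$estimate, 0)
  expect_equal(e$se, 0)
  expect_error(adjusted_difference(d[d$twice == 1, ], "y"), "both arms")
  d$alias <- d$twice  # perfectly collinear with the arm indicator
  expect_error(adjusted_difference(d, "y", adjusters = c("therapy_ipt",
                                                         "alias")), "alias")
})

test_that("longitudinal model recovers a constant arm difference with honest clustering", {
  mk <- function(delta, sd_e = 3, seed = 1) {
    set.seed(seed)
    n <- 300
    base <- data.frame(id = 1:n, twice = rep(0:1, n / 2),
                       therapy_ipt = rbinom(n, 1, 0.5),
                       baseline = rnorm(n, 30, 6), b = rnorm(n, 0, 2))
    long <- merge(expand.grid(id = 1:n, time = c(3, 6, 9, 12)), base)
    long$bdi <- 18 + 0.4 * (long$baseline - 30) + long$b +
      delta * long$twice + rnorm(nrow(long), 0, sd_e)
    long
  }
  e <- longitudinal_effect(mk(-2))
  expect_equal(e$estimate, -2, tolerance = 0.5)
  # identical trajectories: zero effect
  d0 <- mk(0, seed = 2)
  expect_lt(abs(longitudinal_effect(d0)$estimate), 0.75)
  # doubling residual noise widens the interval
  ci1 <- diff(longitudinal_effect(mk(-2, sd_e = 2, seed = 3))$ci)
  ci2 <- diff(longitudinal_effect(mk(-2, sd_e = 4, seed = 3))$ci)
  expect_gt(ci2, ci1)
  expect_error(longitudinal_effect(mk(-2)[0, ]), "post-baseline")
})

test_that("BCa matches exhaustive enumeration on tiny samples", {
  x <- c(2, 5, 7, 11, 23)
  for (stat in list(mean, median)) {
    oracle <- enumerate_bca(x, stat)
    got <- bca_bootstrap(x, stat, exhaustive = TRUE)
    expect_equal(got$t0, oracle$t0)
    expect_equal(got$z0, oracle$z0, tolerance = 1e-12)
    expect_equal(got$a, oracle$a, tolerance = 1e-12)
    expect_equal(got$ci, oracle$ci, tolerance = 1e-12)
  }
})

test_that("BCa approaches the percentile interval on symmetric data", {
  set.seed(10)
  x <- rnorm(500)
  b <- bca_bootstrap(x, mean, B = 2000, seed = 3)
  perc <- unname(quantile(b$replicates, c(0.025, 0.975), type = 7))
  expect_lt(max(abs(b$ci - perc)), 0.05 * sd(x))
  expect_lt(abs(b$z0), 0.1)
  expect_lt(abs(b$a), 0.05)
})

test_that("bootstrap percentile interval agrees with normal theory at large n", {
  set.seed(11)
  x <- rnorm(1000, mean = 5, sd = 2)
  b <- bca_bootstrap(x, mean, B = 2000, seed = 4, accelerated = FALSE)
  norm_ci <- mean(x) + c(-1, 1) * qnorm(0.975) * sd(x) / sqrt(1000)
  expect_lt(max(abs(b$ci - norm_ci)), 0.25 * sd(x) / sqrt(1000) * qnorm(0.975))
})

test_that("degenerate samples collapse the interval to a point", {
  b <- bca_bootstrap(rep(3, 12), mean, B = 200, seed = 1)
  expect_true(b$degenerate)
  expect_equal(b$ci, c(3, 3))
})

test_that("our BCa endpoints agree with an independent implementation", {
  skip_if_not_installed("boot")
  set.seed(12)
  x <- rexp(60)
  ours <- bca_bootstrap(x, mean, B = 4000, seed = 5)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 4000)
  ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_equal(ours$ci, ref, tolerance = 0.05 * sd(x))
})

test_that("MI bootstrap concatenates per-imputation clouds and pools", {
  cfg <- small_config(seed = 30)
  d <- inject_missingness(generate_trial(cfg), cfg)
  fr <- build_analysis_frame(d, aggregate_costs(d))
  imp <- suppressWarnings(mice_pmm(fr, imputation_spec(seed = 2), m = 2))
  stat <- function(dd) {
    X <- cbind(1, dd$twice, dd$therapy_ipt)
    c(delta_cost = stats::lm.fit(X, tbcea:::frame_annual_cost(dd))$coefficients[[2]],
      delta_effect = stats::lm.fit(X, tbcea:::frame_qaly(dd, c(0, 3, 6, 9, 12)))$coefficients[[2]])
  }
  cl <- mi_bootstrap(imp, stat, B = 120, seed = 9)
  expect_equal(nrow(cl), 2 * 120)
  expect_setequal(unique(cl$imputation), 1:2)
  pt <- attr(cl, "point")
  expect_true(pt$delta_cost$ci[1] <= pt$delta_cost$estimate &
                pt$delta_cost$estimate <= pt$delta_cost$ci[2])
  # arm sizes preserved by stratified resampling: replicate stats finite
  expect_true(all(is.finite(cl$delta_cost)))
  # joint resampling preserves the cost-effect correlation direction
  full <- imp$datasets[[1]]
  pc <- cor(tbcea:::frame_annual_cost(full), tbcea:::frame_qaly(full, c(0, 3, 6, 9, 12)))
  cc <- cor(cl$delta_cost, cl$delta_effect)
  expect_equal(sign(pc), sign(cc))
})
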