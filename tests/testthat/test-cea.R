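test_that("ICER reproduces the ratio arithmetic and labels quadrants", {
  r <- icer(2276, -1.36)
  expect_equal(r$icer, 2276 / -1.36)
  expect_equal(abs(r$icer), 1670, tolerance = 0.003 * 1670)
  expect_equal(r$quadrant, "NW")
  expect_equal(icer(0, 0.5)$icer, 0)
  expect_true(is.na(icer(100, 0)$icer))
  for (dc in c(-2, 3)) for (de in c(-0.5, 0.4))
    expect_equal(sign(icer(dc, de)$icer), sign(dc) * sign(de))
})

test_that("quadrant proportions orient the effect axis and sum to one", {
  cl <- data.frame(delta_cost = 1, delta_effect = 1)
  expect_equal(quadrant_proportions(cl),
               c(NE = 1, SE = 0, SW = 0, NW = 0))
  # for a lower-is-better outcome the same pair is unfavourable
  expect_equal(quadrant_proportions(cl, "lower_better")[["NW"]], 1)
  set.seed(2)
  cl <- data.frame(delta_cost = rnorm(500, 1), delta_effect = rnorm(500, -1))
  q <- quadrant_proportions(cl)
  expect_equal(sum(q), 1)
  mirrored <- data.frame(delta_cost = -cl$delta_cost,
                         delta_effect = -cl$delta_effect)
  qm <- quadrant_proportions(mirrored)
  # boundary-free cloud: mirroring swaps NE<->SW and SE<->NW
  expect_equal(unname(qm[c("SW", "NW", "NE", "SE")]), unname(q))
  # invariant to positive rescaling of either axis
  scaled <- data.frame(delta_cost = 250 * cl$delta_cost,
                       delta_effect = 0.01 * cl$delta_effect)
  expect_equal(quadrant_proportions(scaled), q)
  expect_error(quadrant_proportions(cl[0, ]), "empty")
})

test_that("cloud quadrants match closed-form orthant probabilities", {
  set.seed(31)
  n <- 10000
  mu_e <- 0.6
  mu_c <- -0.8
  cl <- data.frame(delta_effect = rnorm(n, mu_e, 1),
                   delta_cost = rnorm(n, mu_c, 1))
  q <- quadrant_proportions(cl)
  pe <- pnorm(mu_e)          # P(effect favourable)
  pc <- pnorm(mu_c)          # P(cost higher)
  expected <- c(NE = pe * pc, SE = pe * (1 - pc),
                SW = (1 - pe) * (1 - pc), NW = (1 - pe) * pc)
  for (k in names(expected)) {
    se <- sqrt(expected[[k]] * (1 - expected[[k]]) / n)
    expect_lt(abs(q[[k]] - expected[[k]]), 4 * se + 1e-6)
  }
})

test_that("net monetary benefit identities hold", {
  expect_equal(nmb(0.5, 1000, 0), -1000)
  expect_equal(nmb(0, 1000, c(0, 5e4)), c(-1000, -1000))
  expect_equal(nmb(0.04, 2000, 2000 / 0.04), 0)  # break-even ceiling ratio
  expect_error(nmb(1, 1, -5), "non-negative")
})

test_that("parametric CEAC follows the normal CDF of pooled NMB", {
  pi1 <- data.frame(delta_effect = 0.5, delta_cost = 0,
                    var_effect = 1e-12, var_cost = 1, cov_ce = 0)
  cv <- ceac_parametric(pi1, lambdas = c(0, 1.96, 10))
  expect_equal(cv$prob[1], 0.5)                 # NMB = 0
  expect_equal(cv$prob[2], pnorm(1.96 * 0.5 / sqrt(1 + 1.96^2 * 1e-12)),
               tolerance = 1e-6)
  # probability crosses 0.5 where the pooled NMB changes sign
  pi2 <- data.frame(delta_effect = 1, delta_cost = 500, var_effect = 0.04,
                    var_cost = 100, cov_ce = 0)
  cv2 <- ceac_parametric(pi2, lambdas = c(499, 500, 501))
  expect_lt(cv2$prob[1], 0.5)
  expect_equal(cv2$prob[2], 0.5)
  expect_gt(cv2$prob[3], 0.5)
  # with a positive pooled effect the curve is non-decreasing
  set.seed(3)
  pi3 <- data.frame(delta_effect = abs(rnorm(4, 1)), delta_cost = rnorm(4),
                    var_effect = 0.1, var_cost = 4, cov_ce = 0)
  cv3 <- ceac_parametric(pi3, lambdas = seq(0, 100, 10))
  expect_true(all(diff(cv3$prob) >= -1e-12))
})

test_that("cloud CEAC limits equal the quadrant masses exactly", {
  set.seed(8)
  cl <- data.frame(delta_cost = rnorm(4000, 200, 500),
                   delta_effect = rnorm(4000, 0.01, 0.05))
  q <- quadrant_proportions(cl)
  cv <- ceac_cloud(cl, lambdas = c(0, 1e9))
  expect_equal(cv$prob[1], mean(cl$delta_cost < 0))
  expect_equal(cv$prob[1], unname(q["SE"] + q["SW"]),
               tolerance = 1e-9 + mean(cl$delta_cost == 0))
  expect_equal(cv$prob[2], unname(q["NE"] + q["SE"]),
               tolerance = mean(cl$delta_effect == 0) + 1e-9)
  # a single pair gives a step function
  one <- data.frame(delta_cost = 100, delta_effect = 0.01)
  step <- ceac_cloud(one, lambdas = c(0, 9999, 10001))
  expect_equal(step$prob, c(0, 0, 1))
})

test_that("parametric and cloud CEACs agree on Gaussian clouds", {
  set.seed(12)
  n <- 10000
  m <- 4
  cl <- data.frame(imputation = rep(1:m, each = n / m),
                   delta_cost = rnorm(n, 300, 900),
                   delta_effect = rnorm(n, 0.02, 0.04))
  per_imp <- do.call(rbind, lapply(split(cl, cl$imputation), function(s)
    data.frame(delta_effect = mean(s$delta_effect),
               delta_cost = mean(s$delta_cost),
               var_effect = var(s$delta_effect), var_cost = var(s$delta_cost),
               cov_ce = cov(s$delta_effect, s$delta_cost))))
  grid <- seq(0, 1e5, length.out = 41)
  p1 <- ceac_parametric(per_imp, grid)
  p2 <- ceac_cloud(cl, grid)
  expect_lt(max(abs(p1$prob - p2$prob)), 0.03)
})

test_that("the default ceiling-ratio grid contains the conventional ratios", {
  g <- lambda_grid()
  expect_true(all(c(0, 1000, 20000, 23000, 34000, 50000) %in% g))
  expect_true(all(diff(g) > 0))
})
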