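# Power function, sample-size inversion, pilot variance scaling.

test_that("power function matches its formula and calibrates at the null", {
  expect_equal(power_rd(135, 0, 0.4294), 0.05, tolerance = 1e-12)
  expect_equal(power_rd(135, 0.139, 0.4294),
               pnorm(0.139 * sqrt(135 / 0.4294) - qnorm(0.95)),
               tolerance = 1e-12)
  expect_equal(power_rd(135, 0.139, 0.4294), 0.7938, tolerance = 1e-4)
  # monotone in n and |delta|, to 1 in the limit
  ns <- c(10, 50, 200, 1000)
  expect_true(all(diff(power_rd(ns, 0.1, 0.4)) > 0))
  expect_gt(power_rd(100, -0.2, 0.4), power_rd(100, -0.1, 0.4))
  expect_equal(power_rd(1e7, 0.1, 0.4), 1, tolerance = 1e-9)
})

test_that("required_n inverts the power function exactly", {
  expect_equal(required_n(0.139, 0.42944, 0.05, 0.8), 138L)
  n <- required_n(0.139, 0.42944)
  expect_gte(power_rd(n, 0.139, 0.42944), 0.8)
  expect_lt(power_rd(n - 1, 0.139, 0.42944), 0.8)
  # quadratic scaling in delta (pre-ceiling)
  zz <- (qnorm(0.95) + qnorm(0.8))^2
  expect_equal(0.42944 * zz / 0.139^2, 4 * 0.42944 * zz / 0.278^2 * 1,
               tolerance = 1e-12)
  expect_error(required_n(0, 0.4), "delta = 0")
  # brute-force scan agreement over random designs
  set.seed(17)
  for (i in 1:25) {
    delta <- runif(1, 0.05, 0.4) * sample(c(-1, 1), 1)
    s2 <- runif(1, 0.1, 0.6)
    a <- runif(1, 0.01, 0.1)
    pw <- runif(1, 0.55, 0.95)
    n <- required_n(delta, s2, a, pw)
    grid <- 2:2000
    brute <- grid[which(power_rd(grid, delta, s2, a) >= pw)[1]]
    expect_identical(n, as.integer(brute))
  }
})

test_that("pilot_variance routes and scales correctly", {
  d <- local({
    spec <- endpoint_spec(1L, FALSE, thresholds = 0)
    y <- c(ifelse(seq_len(87) <= 18, -1, 1), ifelse(seq_len(95) <= 34, -1, 1))
    trial_dataset(seq_len(182), rep(0:1, c(87, 95)), y, NULL, rep(0, 182), spec)
  })
  e <- binary_effects(d)
  s2 <- pilot_variance(e)
  expect_equal(s2, 0.16409 + 0.22981, tolerance = 1e-4)
  # equal pilot arms: sigma2 = var_rd * n exactly
  e2 <- e; e2$method <- "augmented"; e2$var_rd <- 0.004
  e2$n0 <- e2$n1 <- 80L
  expect_equal(pilot_variance(e2), 0.004 * 80, tolerance = 1e-12)
  # doubling both arms with var_rd halved leaves sigma2 unchanged
  e3 <- e2; e3$n0 <- e3$n1 <- 160L; e3$var_rd <- 0.002
  expect_equal(pilot_variance(e3), pilot_variance(e2), tolerance = 1e-12)
  e4 <- e2; e4$var_rd <- -1
  expect_error(pilot_variance(e4), "positive")
})

test_that("power_curve tabulates both routes consistently", {
  pc <- power_curve(0.139, 0.4 * 0.42944, 0.42944)
  expect_s3_class(pc, "sample_size_result")
  expect_lte(pc$n_required_aug, pc$n_required_bin)
  # linear-in-sigma2 scaling before the ceiling
  zz <- (qnorm(0.95) + qnorm(0.8))^2
  expect_equal((0.4 * 0.42944) * zz / 0.139^2,
               0.4 * (0.42944 * zz / 0.139^2), tolerance = 1e-12)
  # curve at the required n reaches target power
  cv <- pc$power_curve
  expect_gte(power_rd(pc$n_required_aug, 0.139, 0.4 * 0.42944), 0.8)
  expect_gte(power_rd(pc$n_required_bin, 0.139, 0.42944), 0.8)
  # degenerate: identical variances give identical curves
  pc2 <- power_curve(0.139, 0.42944, 0.42944, n_grid = c(50L, 100L, 150L))
  expect_identical(pc2$power_curve$power_aug, pc2$power_curve$power_bin)
  expect_error(power_curve(0.139, 0.4, 0.4, n_grid = c(10L, 5L)), "increasing")
})

test_that("simulated trials at required_n attain target power (scaled down)", {
  # empirical validation with the collapsed binary test: simulate at the
  # binomial-route required n under the preset and test RD > 0 one-sided;
  # 150 replicates keeps this inside the budget (3 MC SEs ~ 0.10)
  pre <- sle_preset()
  p0 <- preset_true_prob(pre, 0); p1 <- preset_true_prob(pre, 1)
  delta <- p1 - p0
  s2 <- p0 * (1 - p0) + p1 * (1 - p1)
  n <- required_n(delta, s2, 0.05, 0.8)
  set.seed(99)
  rej <- 0L
  for (r in 1:150) {
    x0 <- rbinom(1, n, p0); x1 <- rbinom(1, n, p1)
    ph0 <- x0 / n; ph1 <- x1 / n
    se <- sqrt(ph0 * (1 - ph0) / n + ph1 * (1 - ph1) / n)
    rej <- rej + ((ph1 - ph0) / se > qnorm(0.95))
  }
  expect_gt(rej / 150, 0.8 - 3 * sqrt(0.8 * 0.2 / 150))
})
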