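# Likelihood, fitting, response probabilities and goodness of fit.

test_that("log-likelihood matches hand values and is translation invariant", {
  spec <- endpoint_spec(2L, TRUE, c(-4, 0.3))
  params <- latent_parameters(alpha = c(1, -2), beta = c(0, 0),
                              gamma = c(0, 0), sigma = c(1, 1),
                              alpha_b = 0, beta_b = 0, R = diag(3))
  d <- trial_dataset("a", 0, cbind(1, -2), 1L, cbind(0, 0), spec)
  # independent standard normals at their means, binary at latent mean 0:
  # 2 log(1/sqrt(2 pi)) + log(1/2)
  expect_equal(loglikelihood(params, d), -log(2 * pi) - log(2),
               tolerance = 1e-7)
  expect_equal(loglikelihood(params, d), -2.5310243, tolerance = 1e-6)
  # location family: shift y1 and alpha1 together
  set.seed(8)
  pre <- sle_preset()
  dd <- generate_trial(pre$params, 30, pre$baseline_law, pre$spec, seed = 3)
  base_ll <- loglikelihood(pre$params, dd)
  shifted <- pre$params; shifted$alpha[1] <- shifted$alpha[1] + 11.3
  dd2 <- dd; dd2$y_cont[, 1] <- dd2$y_cont[, 1] + 11.3
  expect_equal(loglikelihood(shifted, dd2), base_ll, tolerance = 1e-8)
})

test_that("closed-form likelihood equals the latent-integration oracle", {
  spec <- endpoint_spec(2L, TRUE, c(-4, 0.3))
  set.seed(42)
  for (rep in 1:8) {
    params <- random_params()
    d <- generate_trial(params, 4,
                        list(mean = c(0, 0), sd = c(1, 1)), spec,
                        seed = 100 + rep)
    expect_equal(loglikelihood(params, d), oracle_loglik(params, d),
                 tolerance = 1e-6)
  }
})

test_that("with one continuous component and no binary the MLE is OLS", {
  spec <- endpoint_spec(1L, FALSE, thresholds = -1)
  set.seed(5)
  n <- 120
  arm <- rep(0:1, each = n / 2)
  base <- rnorm(n, 2, 1)
  y <- 0.5 - 0.8 * arm + 0.4 * base + rnorm(n, 0, 1.3)
  d <- trial_dataset(seq_len(n), arm, y, NULL, base, spec)
  fit <- fit_latent_model(d)
  ols <- lm(y ~ arm + base)
  expect_equal(unname(fit$params$alpha), unname(coef(ols)[1]), tolerance = 1e-6)
  expect_equal(unname(fit$params$beta), unname(coef(ols)[2]), tolerance = 1e-6)
  expect_equal(unname(fit$params$gamma), unname(coef(ols)[3]), tolerance = 1e-6)
  # MLE scale (divisor n, not n - p)
  expect_equal(fit$params$sigma,
               sqrt(sum(residuals(ols)^2) / n), tolerance = 1e-6)
  # response probability collapses to the probit of the standardised threshold
  p <- response_probability(fit$params, 0, matrix(1.7), spec)
  mu <- fit$params$alpha + fit$params$gamma * 1.7
  expect_equal(p, pnorm((-1 - mu) / fit$params$sigma), tolerance = 1e-9)
})

test_that("response_probability factorises under independence and is monotone", {
  spec <- endpoint_spec(2L, TRUE, c(-4, 0.3))
  params <- latent_parameters(alpha = c(-4.5, 0), beta = c(-1, 0),
                              gamma = c(0.3, 0.2), sigma = c(4, 0.5),
                              alpha_b = -0.2, beta_b = 0.3, R = diag(3))
  bl <- rbind(c(10, 1.8), c(8, 1.4))
  for (arm in 0:1) {
    p <- response_probability(params, arm, bl, spec)
    marg <- sapply(1:2, function(j) {
      mu <- params$alpha[j] + params$beta[j] * arm + params$gamma[j] * bl[, j]
      pnorm((spec$thresholds[j] - mu) / params$sigma[j])
    })
    pb <- pnorm(params$alpha_b + params$beta_b * arm)
    expect_equal(p, mean(marg[, 1] * marg[, 2] * pb), tolerance = 1e-9)
  }
  # near-infinite thresholds exhaust the continuous mass
  spec_wide <- endpoint_spec(2L, FALSE, c(1e6, 1e6))
  params_nb <- latent_parameters(alpha = c(-4.5, 0), beta = c(-1, 0),
                                 gamma = c(0.3, 0.2), sigma = c(4, 0.5),
                                 R = diag(2))
  expect_equal(response_probability(params_nb, 0, bl, spec_wide), 1,
               tolerance = 1e-10)
  # monotone in thresholds and in the binary treatment lift
  pre <- sle_preset()
  set.seed(6)
  B <- cbind(rnorm(50, 10, 3), rnorm(50, 1.8, 0.4))
  p_ref <- response_probability(pre$params, 1, B, pre$spec)
  spec_up <- endpoint_spec(2L, TRUE, pre$spec$thresholds + c(0.5, 0.1))
  expect_gte(response_probability(pre$params, 1, B, spec_up), p_ref)
  par_up <- pre$params; par_up$beta_b <- par_up$beta_b + 0.4
  expect_gte(response_probability(par_up, 1, B, pre$spec), p_ref)
  expect_gte(p_ref, 0); expect_lte(p_ref, 1)
})

test_that("response_probability agrees with its exact marginal closed form", {
  pre <- sle_preset()
  set.seed(9)
  nb <- 40000
  B <- cbind(rnorm(nb, pre$baseline_law$mean[1], pre$baseline_law$sd[1]),
             rnorm(nb, pre$baseline_law$mean[2], pre$baseline_law$sd[2]))
  for (arm in 0:1) {
    exact <- preset_true_prob(pre, arm)
    avg <- response_probability(pre$params, arm, B, pre$spec)
    # baseline-sampling error only; ~3 MC SEs of the baseline average
    expect_equal(avg, exact, tolerance = 3 * 0.2 / sqrt(nb) / exact)
  }
})

test_that("maximum likelihood recovers generating parameters (single large run)", {
  pre <- sle_preset()
  d <- generate_trial(pre$params, 2000, pre$baseline_law, pre$spec, seed = 77)
  fit <- fit_latent_model(d)
  expect_true(fit$converged)
  expect_gte(fit$loglik, loglikelihood(pre$params, d))
  th_true <- latentresp:::params_to_theta(pre$params)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$theta - th_true) <= 3 * se))
  # correlations live in (-1, 1)
  est_R <- fit$params$R
  expect_true(all(abs(est_R[upper.tri(est_R)]) < 1))
})

test_that("fit guard rails fire", {
  pre <- sle_preset()
  d <- generate_trial(pre$params, 8, pre$baseline_law, pre$spec, seed = 1)
  expect_error(fit_latent_model(d), "at least 10")
  d2 <- generate_trial(pre$params, 30, pre$baseline_law, pre$spec, seed = 2)
  d2$y_bin <- rep(1L, length(d2$y_bin))
  expect_error(fit_latent_model(d2), "separation")
  # tiny-but-legal dataset: MLE beats the truth by definition of maximiser
  d3 <- generate_trial(pre$params, 30, pre$baseline_law, pre$spec, seed = 3)
  fit3 <- suppressWarnings(fit_latent_model(d3))
  expect_gte(fit3$loglik, loglikelihood(pre$params, d3))
})

test_that("goodness-of-fit residuals are Mahalanobis distances with chi-squared reference", {
  pre <- sle_preset()
  d <- generate_trial(pre$params, 150, pre$baseline_law, pre$spec, seed = 21)
  fit <- fit_latent_model(d)
  g <- gof_residuals(fit)
  expect_equal(g$df, 2L)
  expect_equal(length(g$residuals), length(d$arm))
  # recompute directly from the fitted parameters
  e <- latentresp:::.std_resid(fit$params, d)
  d2 <- rowSums((e %*% solve(fit$params$R[1:2, 1:2])) * e)
  expect_equal(g$residuals, sort(d2), tolerance = 1e-10)
  expect_equal(g$theoretical,
               qchisq((seq_along(d2) - 0.5) / length(d2), df = 2))
  # identity continuous correlation: residual is the sum of squared
  # standardised residuals
  params_id <- fit$params
  params_id$R[1, 2] <- params_id$R[2, 1] <- 0
  fit_id <- fit; fit_id$params <- params_id
  g_id <- gof_residuals(fit_id)
  e_id <- latentresp:::.std_resid(params_id, d)
  expect_equal(g_id$residuals, sort(rowSums(e_id^2)), tolerance = 1e-10)
})

test_that("gof KS distance is calibrated when the model is true", {
  # scaled down from 100 replicates at 1000 subjects to fit the test budget:
  # 40 replicates at 500 subjects, same 1% critical-value check
  pre <- sle_preset()
  crit <- 1.628 / sqrt(500)  # asymptotic 1% KS critical value
  ok <- 0L
  for (r in 1:40) {
    d <- generate_trial(pre$params, 250, pre$baseline_law, pre$spec,
                        seed = 4000 + r)
    fit <- try(fit_latent_model(d), silent = TRUE)
    if (inherits(fit, "try-error")) next
    g <- gof_residuals(fit)
    ok <- ok + (g$ks_distance < crit)
  }
  expect_gte(ok, ceiling(0.95 * 40))
})
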