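# Shared fixtures and independent oracles.  Everything is generated in code;
# no stored data.

# Small hand-made dataset: 2 continuous + 1 binary, thresholds (-4, 0.3).
tiny_dataset <- function() {
  spec <- endpoint_spec(2L, TRUE, thresholds = c(-4, 0.3),
                        inclusive = c(TRUE, FALSE))
  trial_dataset(
    subject_id = paste0("P", 1:6),
    arm = c(0, 0, 0, 1, 1, 1),
    y_cont = rbind(c(-5, 0.1), c(-3, 0.1), c(-4, 0.3),
                   c(-6, -0.2), c(-4.5, 0.25), c(-2, 0.5)),
    y_bin = c(1, 1, 1, 1, 0, 1),
    baselines = rbind(c(9, 1.5), c(11, 2.0), c(10, 1.8),
                      c(12, 1.6), c(8, 1.9), c(10, 2.1)),
    spec = spec)
}

# Random valid latent parameters for a given structure (seeded by caller).
random_params <- function(n_cont = 2L, has_binary = TRUE) {
  d <- n_cont + as.integer(has_binary)
  repeat {
    R <- diag(d)
    if (d > 1L) {
      z <- stats::runif(choose(d, 2L), -0.6, 0.6)
      R[upper.tri(R)] <- z
      R[lower.tri(R)] <- t(R)[lower.tri(R)]
    }
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > 0.05)
      break
  }
  latent_parameters(
    alpha = stats::rnorm(n_cont, 0, 2),
    beta = stats::rnorm(n_cont, 0, 1),
    gamma = stats::rnorm(n_cont, 0, 0.5),
    sigma = stats::runif(n_cont, 0.5, 3),
    alpha_b = if (has_binary) stats::rnorm(1, 0, 0.5) else NULL,
    beta_b = if (has_binary) stats::rnorm(1, 0, 0.5) else NULL,
    R = R)
}

# Independent log-likelihood oracle: full joint density of (y_cont, latent)
# with the latent integrated numerically over its half-line.  Uses generic
# matrix algebra (solve/determinant), not the production conditional
# factorisation.
oracle_loglik <- function(params, data) {
  nc <- params$n_cont
  d <- nc + 1L
  S <- diag(c(params$sigma, 1)) %*% params$R %*% diag(c(params$sigma, 1))
  Sinv <- solve(S)
  logdet <- determinant(S, logarithm = TRUE)$modulus
  dens3 <- function(v, mu) {
    e <- v - mu
    exp(-0.5 * (d * log(2 * pi) + logdet + sum(e * (Sinv %*% e))))
  }
  total <- 0
  for (i in seq_along(data$arm)) {
    mu <- vapply(seq_len(nc), function(j)
      params$alpha[j] + params$beta[j] * data$arm[i] +
        params$gamma[j] * data$baselines[i, j], numeric(1))
    mu <- c(mu, params$alpha_b + params$beta_b * data$arm[i])
    f <- function(l) vapply(l, function(li)
      dens3(c(data$y_cont[i, ], li), mu), numeric(1))
    lik <- if (data$y_bin[i] == 1L)
      stats::integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 1e-13)$value
    else
      stats::integrate(f, -Inf, 0, rel.tol = 1e-10, abs.tol = 1e-13)$value
    total <- total + log(lik)
  }
  total
}

# Exact marginal (over the baseline law) response probability for the
# SLE-like preset: because baselines are Gaussian and enter linearly, the
# marginal joint law of (Y1, Y2, latent) is again trivariate normal, so the
# marginal response probability is a single box probability with inflated
# scales.  Independent of the G-computation path in response_probability.
preset_true_prob <- function(preset, arm) {
  p <- preset$params; bl <- preset$baseline_law; spec <- preset$spec
  sd_tot <- sqrt(p$sigma^2 + p$gamma^2 * bl$sd^2)
  u <- (spec$thresholds - p$alpha - p$beta * arm - p$gamma * bl$mean) / sd_tot
  u3 <- p$alpha_b + p$beta_b * arm
  r12 <- p$sigma[1] * p$sigma[2] * p$R[1, 2] / (sd_tot[1] * sd_tot[2])
  r1b <- p$sigma[1] * p$R[1, 3] / sd_tot[1]
  r2b <- p$sigma[2] * p$R[2, 3] / sd_tot[2]
  Rstar <- rbind(c(1, r12, -r1b), c(r12, 1, -r2b), c(-r1b, -r2b, 1))
  ptvnorm(u[1], u[2], u3, Rstar, nodes = 48L)
}

# Null preset: SLE-like structure with every treatment effect removed.
null_preset <- function() {
  pre <- sle_preset()
  pre$params$beta <- c(0, 0)
  pre$params$beta_b <- 0
  pre
}
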