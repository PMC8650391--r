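# Joint latent-Gaussian model of a composite responder endpoint.
#
# The continuous components follow a multivariate normal regression with a
# baseline covariate per component; the binary component is generated by a
# unit-variance latent Gaussian (probit) with intercept and treatment terms
# only.  All latent residuals share one correlation matrix R, which is what
# couples the components.  The observed-data likelihood factorises as the
# multivariate normal density of the continuous outcomes times the
# conditional probit probability of the binary outcome given them, so no
# numerical integration is needed to evaluate it.

#' Parameters of the latent-Gaussian composite endpoint model
#'
#' For continuous component j: outcome
#' \eqn{Y_j = \alpha_j + \beta_j \cdot arm + \gamma_j \cdot baseline_j + \sigma_j \epsilon_j}.
#' For the binary component: response indicator
#' \eqn{1\{\alpha_b + \beta_b \cdot arm + \epsilon_b > 0\}} with
#' \eqn{\epsilon_b} standard normal (probit scale).  The standardised
#' residuals \eqn{(\epsilon_1, ..., \epsilon_b)} are jointly normal with
#' correlation matrix `R`, ordered continuous components first, binary
#' latent last.
#'
#' @param alpha,beta,gamma Numeric vectors of length `n_cont`: intercept,
#'   treatment and baseline coefficients per continuous component.
#' @param sigma Positive residual scales, length `n_cont`.
#' @param alpha_b,beta_b Latent intercept and treatment coefficient of the
#'   binary component (probit scale); `NULL` when there is none.
#' @param R Correlation matrix over the latent residuals
#'   (`n_cont + has_binary` dimensions); symmetric, unit diagonal, positive
#'   definite.
#' @return An object of class `latent_parameters`.
#' @export
latent_parameters <- function(alpha, beta, gamma, sigma,
                              alpha_b = NULL, beta_b = NULL, R) {
  n_cont <- length(alpha)
  stopifnot(n_cont %in% 1:2,
            length(beta) == n_cont, length(gamma) == n_cont,
            length(sigma) == n_cont)
  if (any(sigma <= 0)) stop("residual scales sigma must be positive")
  has_binary <- !is.null(alpha_b)
  if (has_binary) stopifnot(length(alpha_b) == 1L, length(beta_b) == 1L)
  d <- n_cont + as.integer(has_binary)
  R <- as.matrix(R)
  if (!all(dim(R) == d)) stop("R must be ", d, "x", d)
  if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8)
    stop("R must be symmetric with unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10)
    stop("R is not positive definite")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.numeric(gamma), sigma = as.numeric(sigma),
                 alpha_b = alpha_b, beta_b = beta_b,
                 R = unname((R + t(R)) / 2),
                 n_cont = n_cont, has_binary = has_binary),
            class = "latent_parameters")
}

#' @export
print.latent_parameters <- function(x, ...) {
  cat("Latent-Gaussian composite endpoint model parameters\n")
  for (j in seq_len(x$n_cont))
    cat(sprintf("  cont %d: alpha=%.4g beta=%.4g gamma=%.4g sigma=%.4g\n",
                j, x$alpha[j], x$beta[j], x$gamma[j], x$sigma[j]))
  if (x$has_binary)
    cat(sprintf("  binary (probit latent): alpha_b=%.4g beta_b=%.4g\n",
                x$alpha_b, x$beta_b))
  cat("  residual correlation matrix:\n")
  print(round(x$R, 4))
  invisible(x)
}

# ---- unconstrained parameterisation -----------------------------------------
# theta = (alpha_j, beta_j, gamma_j, log sigma_j)_{j=1..n_cont},
#         (alpha_b, beta_b) if binary,
#         correlation angles z (hyperspherical Cholesky of R).
# Angles phi in (0, pi) are mapped from the real line by phi = pi * plogis(z),
# guaranteeing a positive-definite R for every theta.

corr_from_angles <- function(z, d) {
  phi <- pi * stats::plogis(z)
  L <- diag(d)
  if (d == 2L) {
    L[2, 1] <- cos(phi[1]); L[2, 2] <- sin(phi[1])
  } else if (d == 3L) {
    L[2, 1] <- cos(phi[1]); L[2, 2] <- sin(phi[1])
    L[3, 1] <- cos(phi[2])
    L[3, 2] <- sin(phi[2]) * cos(phi[3])
    L[3, 3] <- sin(phi[2]) * sin(phi[3])
  }
  tcrossprod(L)
}

angles_from_corr <- function(R) {
  d <- nrow(R)
  if (d == 1L) return(numeric(0))
  L <- t(chol(R))
  clamp <- function(x) max(-1 + 1e-10, min(1 - 1e-10, x))
  if (d == 2L) {
    phi <- acos(clamp(L[2, 1]))
  } else {
    phi1 <- acos(clamp(L[2, 1]))
    phi2 <- acos(clamp(L[3, 1]))
    phi3 <- acos(clamp(L[3, 2] / max(sin(phi2), 1e-10)))
    phi <- c(phi1, phi2, phi3)
  }
  stats::qlogis(phi / pi)
}

n_theta <- function(spec) {
  d <- n_latent(spec)
  4L * spec$n_cont + 2L * as.integer(spec$has_binary) + choose(d, 2L)
}

params_to_theta <- function(params) {
  d <- params$n_cont + as.integer(params$has_binary)
  th <- c(rbind(params$alpha, params$beta, params$gamma, log(params$sigma)))
  if (params$has_binary) th <- c(th, params$alpha_b, params$beta_b)
  c(th, if (d > 1L) angles_from_corr(params$R))
}

theta_to_params <- function(theta, spec) {
  nc <- spec$n_cont
  m <- matrix(theta[seq_len(4L * nc)], nrow = 4L)
  i <- 4L * nc
  if (spec$has_binary) {
    ab <- theta[i + 1L]; bb <- theta[i + 2L]; i <- i + 2L
  } else ab <- bb <- NULL
  d <- n_latent(spec)
  R <- if (d > 1L) corr_from_angles(theta[(i + 1L):length(theta)], d)
       else matrix(1, 1, 1)
  latent_parameters(alpha = m[1L, ], beta = m[2L, ], gamma = m[3L, ],
                    sigma = exp(m[4L, ]), alpha_b = ab, beta_b = bb, R = R)
}

theta_names <- function(spec) {
  nms <- c(t(outer(seq_len(spec$n_cont),
                   c("alpha", "beta", "gamma", "log_sigma"),
                   function(j, s) paste0(s, j))))
  if (spec$has_binary) nms <- c(nms, "alpha_b", "beta_b")
  d <- n_latent(spec)
  if (d > 1L) nms <- c(nms, paste0("corr_z", seq_len(choose(d, 2L))))
  nms
}

# ---- likelihood -------------------------------------------------------------

# Standardised continuous residuals (n x n_cont) under params.
.std_resid <- function(params, data) {
  nc <- params$n_cont
  e <- matrix(0, length(data$arm), nc)
  for (j in seq_len(nc)) {
    mu <- params$alpha[j] + params$beta[j] * data$arm +
      params$gamma[j] * data$baselines[, j]
    e[, j] <- (data$y_cont[, j] - mu) / params$sigma[j]
  }
  e
}

#' Observed-data log-likelihood of the latent model
#'
#' Sum over subjects of the log multivariate-normal density of the
#' continuous outcomes plus, when a binary component is present, the log
#' conditional probit probability of the observed binary outcome given the
#' continuous outcomes.  Subjects whose continuous readings sit close to a
#' threshold therefore contribute partial information to the binary latent,
#' which is where the efficiency gain over the collapsed analysis comes
#' from.
#'
#' @param params A [latent_parameters()] object.
#' @param data A [trial_dataset()].
#' @param spec An [endpoint_spec()]; defaults to the dataset's.
#' @return The log-likelihood (a single number).
#' @export
loglikelihood <- function(params, data, spec = data$spec) {
  stopifnot(inherits(params, "latent_parameters"),
            inherits(data, "trial_dataset"))
  if (params$n_cont != spec$n_cont || params$has_binary != spec$has_binary)
    stop("params do not match the endpoint structure")
  nc <- params$n_cont
  e <- .std_resid(params, data)
  if (nc == 1L) {
    ll <- sum(stats::dnorm(e[, 1L], log = TRUE)) -
      length(e[, 1L]) * log(params$sigma[1L])
  } else {
    r <- params$R[1L, 2L]
    omr2 <- 1 - r^2
    q <- (e[, 1L]^2 - 2 * r * e[, 1L] * e[, 2L] + e[, 2L]^2) / omr2
    ll <- sum(-log(2 * pi) - log(params$sigma[1L]) - log(params$sigma[2L]) -
                0.5 * log(omr2) - 0.5 * q)
  }
  if (params$has_binary) {
    rho_b <- params$R[seq_len(nc), nc + 1L]
    Rcc <- params$R[seq_len(nc), seq_len(nc), drop = FALSE]
    a <- solve(Rcc, rho_b)
    s2 <- 1 - sum(rho_b * a)
    if (s2 <= 0) stop("latent correlation matrix is not positive definite")
    m <- params$alpha_b + params$beta_b * data$arm + drop(e %*% a)
    qs <- 2 * data$y_bin - 1
    ll <- ll + sum(stats::pnorm(qs * m / sqrt(s2), log.p = TRUE))
  }
  ll
}

.negloglik_theta <- function(theta, data, spec) {
  p <- try(theta_to_params(theta, spec), silent = TRUE)
  if (inherits(p, "try-error")) return(1e10)
  ll <- try(loglikelihood(p, data, spec), silent = TRUE)
  if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
  -ll
}

# central-difference gradient, relative step
.num_grad <- function(f, x, rel_step = 1e-5, ...) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- rel_step * (abs(x[i]) + rel_step)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp, ...) - f(xm, ...)) / (2 * h)
  }
  g
}

# least-squares / probit initial values
.init_theta <- function(data, spec) {
  nc <- spec$n_cont
  resid <- matrix(0, length(data$arm), nc + as.integer(spec$has_binary))
  th <- numeric(0)
  for (j in seq_len(nc)) {
    fit <- stats::lm.fit(cbind(1, data$arm, data$baselines[, j]),
                         data$y_cont[, j])
    s <- sqrt(sum(fit$residuals^2) / length(fit$residuals))
    th <- c(th, fit$coefficients, log(s))
    resid[, j] <- fit$residuals / s
  }
  if (spec$has_binary) {
    g <- suppressWarnings(
      stats::glm.fit(cbind(1, data$arm), data$y_bin,
                     family = stats::binomial("probit")))
    cf <- g$coefficients
    cf[!is.finite(cf)] <- 0
    cf <- pmin(3, pmax(-3, cf))
    th <- c(th, cf)
    phat <- stats::pnorm(cbind(1, data$arm) %*% cf)
    resid[, nc + 1L] <- (data$y_bin - phat) / sqrt(pmax(phat * (1 - phat), 1e-4))
  }
  d <- n_latent(spec)
  if (d > 1L) {
    R0 <- stats::cor(resid)
    R0[upper.tri(R0)] <- pmin(0.9, pmax(-0.9, R0[upper.tri(R0)]))
    R0[lower.tri(R0)] <- t(R0)[lower.tri(R0)]
    # shrink toward identity until positive definite
    lam <- 1
    while (min(eigen(R0 * lam + diag(d) * (1 - lam), symmetric = TRUE,
                     only.values = TRUE)$values) < 1e-6) lam <- lam * 0.9
    th <- c(th, angles_from_corr(R0 * lam + diag(d) * (1 - lam)))
  }
  th
}

#' Fit the latent-Gaussian composite endpoint model by maximum likelihood
#'
#' Maximises the observed-data log-likelihood over an unconstrained
#' parameterisation (log residual scales; hyperspherical-Cholesky angles for
#' the correlation matrix, which keeps it positive definite throughout).
#' Starting values come from per-component least squares, a probit
#' regression for the binary part, and clipped residual correlations.  The
#' covariance of the estimator is the inverse of the numerically
#' differentiated observed information at the optimum.
#'
#' @param data A [trial_dataset()].
#' @param spec An [endpoint_spec()]; defaults to the dataset's.
#' @param control Optimiser settings: `maxit` (default 500), `reltol`
#'   (default 1e-12), `grad_tol` for the reported gradient check (default
#'   1e-3 on the score scale), and optionally `init` (an unconstrained
#'   starting vector, e.g. a previous fit's `theta`, used by bootstrap
#'   refits).
#' @return An object of class `latent_fit` with elements `params` (the MLE
#'   as [latent_parameters()]), `theta` (unconstrained MLE), `loglik`,
#'   `vcov` (unconstrained scale), `converged`, `n_iter`, `gradient_norm`,
#'   and the data/spec used.
#' @export
fit_latent_model <- function(data, spec = data$spec, control = list()) {
  stopifnot(inherits(data, "trial_dataset"))
  n0 <- sum(data$arm == 0); n1 <- sum(data$arm == 1)
  if (n0 < 10L || n1 < 10L)
    stop("need at least 10 subjects per arm (have ", n0, " control, ",
         n1, " treatment)")
  if (spec$has_binary) {
    tab <- table(factor(data$y_bin, levels = 0:1))
    if (any(tab == 0L))
      stop("binary component shows complete separation (all ",
           names(tab)[tab > 0L], "); the probit latent is not identifiable")
  }
  ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-12, grad_tol = 1e-3),
                           control)
  th0 <- if (!is.null(ctl$init)) ctl$init else .init_theta(data, spec)
  if (length(th0) != n_theta(spec))
    stop("control$init has wrong length; expected ", n_theta(spec))
  opt <- stats::optim(th0, .negloglik_theta, data = data, spec = spec,
                      method = "BFGS",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  # one polish pass; BFGS restarts help when the first run stops early
  opt2 <- stats::optim(opt$par, .negloglik_theta, data = data, spec = spec,
                       method = "BFGS",
                       control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  if (opt2$value <= opt$value) opt <- opt2
  if (opt$value >= 1e9)
    stop("likelihood optimisation failed; best value non-finite")
  theta <- opt$par
  g <- .num_grad(.negloglik_theta, theta, data = data, spec = spec)
  H <- stats::optimHess(theta, .negloglik_theta, data = data, spec = spec)
  H <- (H + t(H)) / 2
  V <- try(solve(H), silent = TRUE)
  ok_vcov <- !inherits(V, "try-error") && all(is.finite(V)) &&
    all(diag(V) > 0)
  if (!ok_vcov) {
    ev <- eigen(H, symmetric = TRUE)
    lam <- pmax(ev$values, max(abs(ev$values)) * 1e-8)
    V <- ev$vectors %*% diag(1 / lam, length(lam)) %*% t(ev$vectors)
  }
  V <- (V + t(V)) / 2
  converged <- opt$convergence == 0L && sqrt(sum(g^2)) <
    ctl$grad_tol * max(1, abs(opt$value))
  if (opt$convergence != 0L)
    stop("optimiser did not converge after ", ctl$maxit,
         " iterations; best loglik ", format(-opt$value),
         ", gradient norm ", format(sqrt(sum(g^2))))
  dimnames(V) <- list(theta_names(spec), theta_names(spec))
  names(theta) <- theta_names(spec)
  structure(list(params = theta_to_params(theta, spec),
                 theta = theta, loglik = -opt$value, vcov = V,
                 converged = converged,
                 n_iter = unname(opt$counts["function"]),
                 gradient_norm = sqrt(sum(g^2)),
                 data = data, spec = spec),
            class = "latent_fit")
}

#' @export
print.latent_fit <- function(x, ...) {
  cat(sprintf("Latent-model fit: loglik %.4f, %s (%d evaluations, |grad| %.2e)\n",
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$gradient_norm))
  print(x$params)
  invisible(x)
}

#' Model-based probability of overall response
#'
#' The probability that a subject in the given arm responds on every
#' component simultaneously: all continuous outcomes below their thresholds
#' and the binary latent above zero.  This is a box probability of the joint
#' latent-Gaussian distribution, computed deterministically and averaged
#' over the supplied baseline rows (marginal standardisation / G-computation
#' when the empirical baselines of all subjects are used).
#'
#' @param params A [latent_parameters()] object.
#' @param arm 0 (control) or 1 (treatment).
#' @param baselines Matrix of baseline rows (one column per continuous
#'   component) to average over; a single row gives an at-covariate
#'   evaluation.
#' @param spec An [endpoint_spec()].
#' @return A probability in `[0, 1]`.
#' @export
response_probability <- function(params, arm, baselines, spec) {
  stopifnot(inherits(params, "latent_parameters"),
            inherits(spec, "endpoint_spec"), arm %in% c(0, 1))
  baselines <- as.matrix(baselines)
  if (nrow(baselines) == 0L) stop("baselines must be non-empty")
  if (ncol(baselines) != params$n_cont)
    stop("baselines must have one column per continuous component")
  nc <- params$n_cont
  u <- matrix(0, nrow(baselines), nc)
  for (j in seq_len(nc)) {
    mu <- params$alpha[j] + params$beta[j] * arm +
      params$gamma[j] * baselines[, j]
    u[, j] <- (spec$thresholds[j] - mu) / params$sigma[j]
  }
  if (!params$has_binary) {
    p <- if (nc == 1L) stats::pnorm(u[, 1L])
         else pbvnorm(u[, 1L], u[, 2L], params$R[1L, 2L])
    return(mean(pmin(1, pmax(0, p))))
  }
  # binary response: latent alpha_b + beta_b*arm + e_b > 0, i.e.
  # Z3 = -e_b <= u3 with u3 = alpha_b + beta_b*arm; corr(Z3, e_j) = -rho_jb.
  u3 <- params$alpha_b + params$beta_b * arm
  rho_b <- params$R[seq_len(nc), nc + 1L]
  if (nc == 1L) {
    p <- pbvnorm(u[, 1L], u3, -rho_b[1L])
  } else {
    Rstar <- rbind(c(1, params$R[1L, 2L], -rho_b[1L]),
                   c(params$R[1L, 2L], 1, -rho_b[2L]),
                   c(-rho_b[1L], -rho_b[2L], 1))
    p <- ptvnorm(u[, 1L], u[, 2L], u3, Rstar)
  }
  mean(pmin(1, pmax(0, p)))
}

#' Goodness-of-fit residuals for the continuous block
#'
#' Squared Mahalanobis residuals of the continuous outcomes against their
#' fitted means and covariance.  Under a correct model these follow a
#' chi-squared distribution with `n_cont` degrees of freedom; the returned
#' theoretical quantiles (at plotting positions \eqn{(i - 0.5)/n}) support a
#' QQ plot against that law, and the Kolmogorov-Smirnov distance summarises
#' the discrepancy.
#'
#' @param fit A converged [fit_latent_model()] result.
#' @return A list with `residuals` (sorted squared Mahalanobis residuals),
#'   `theoretical` (matching chi-squared quantiles), `df`, and `ks_distance`.
#' @export
gof_residuals <- function(fit) {
  stopifnot(inherits(fit, "latent_fit"))
  if (!fit$converged) stop("goodness of fit requires a converged fit")
  params <- fit$params
  e <- .std_resid(params, fit$data)
  nc <- params$n_cont
  if (nc == 1L) {
    d2 <- e[, 1L]^2
  } else {
    Rcc <- params$R[1:2, 1:2]
    Rinv <- solve(Rcc)
    d2 <- rowSums((e %*% Rinv) * e)
  }
  d2 <- sort(d2)
  n <- length(d2)
  theo <- stats::qchisq((seq_len(n) - 0.5) / n, df = nc)
  Fx <- stats::pchisq(d2, df = nc)
  ks <- max(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n)
  list(residuals = d2, theoretical = theo, df = nc, ks_distance = ks)
}
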