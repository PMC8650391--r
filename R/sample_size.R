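# Power and per-arm sample size for a future trial analysed by either
# route, driven by pilot estimates.  The test is a one-sided z-test on the
# risk difference with equal allocation and variance law Var(RD) =
# sigma2_tot / n per arm; pilot data supply delta and sigma2_tot.

#' One-sided normal-approximation power for the risk-difference test
#'
#' \eqn{\Phi(|\delta| \sqrt{n / \sigma^2_{tot}} - z_{1-\alpha})}: the power
#' of a one-sided level-\eqn{\alpha} z-test oriented in the direction of the
#' anticipated effect, with `n` subjects per arm and
#' \eqn{Var(\hat{RD}) = \sigma^2_{tot} / n}.  At \eqn{\delta = 0} this is
#' exactly \eqn{\alpha}.
#'
#' @param n Per-arm sample size (vectorised), at least 2.
#' @param delta Anticipated risk difference.
#' @param sigma2_tot Per-arm-normalised variance sum (e.g.
#'   \eqn{p_0(1-p_0) + p_1(1-p_1)} for the unadjusted binary route).
#' @param alpha One-sided significance level.
#' @return Power in `(0, 1)`, same length as `n`.
#' @export
power_rd <- function(n, delta, sigma2_tot, alpha = 0.05) {
  stopifnot(all(n >= 2), sigma2_tot > 0, alpha > 0, alpha < 0.5)
  stats::pnorm(abs(delta) * sqrt(n / sigma2_tot) - stats::qnorm(1 - alpha))
}

#' Smallest per-arm sample size achieving a target power
#'
#' Closed form \eqn{\lceil \sigma^2_{tot} (z_{1-\alpha} + z_{power})^2 /
#' \delta^2 \rceil}, verified by inverting [power_rd()]: the returned `n`
#' satisfies `power_rd(n) >= target_power` and `power_rd(n - 1) <
#' target_power` (subject to the floor of 2 per arm).
#'
#' @param delta Anticipated risk difference; must be non-zero.
#' @param sigma2_tot Per-arm-normalised variance sum.
#' @param alpha One-sided significance level.
#' @param target_power Target power in `(0.5, 1)`.
#' @return Integer per-arm sample size, at least 2.
#' @export
required_n <- function(delta, sigma2_tot, alpha = 0.05, target_power = 0.8) {
  stopifnot(sigma2_tot > 0, alpha > 0, alpha < 0.5,
            target_power > 0.5, target_power < 1)
  if (delta == 0)
    stop("delta = 0: no finite sample size attains the target power")
  zz <- stats::qnorm(1 - alpha) + stats::qnorm(target_power)
  n <- as.integer(ceiling(sigma2_tot * zz^2 / delta^2 - 1e-9))
  n <- max(n, 2L)
  # guard the closed form against rounding at the boundary
  while (n > 2L && power_rd(n - 1L, delta, sigma2_tot, alpha) >= target_power)
    n <- n - 1L
  while (power_rd(n, delta, sigma2_tot, alpha) < target_power)
    n <- n + 1L
  n
}

#' Per-arm-normalised variance from pilot estimates
#'
#' Converts pilot-trial estimates into the \eqn{\sigma^2_{tot}} of the
#' variance law \eqn{Var(\hat{RD}) = \sigma^2_{tot}/n}.  The binomial route
#' uses \eqn{\hat{p}_0(1-\hat{p}_0) + \hat{p}_1(1-\hat{p}_1)}; the
#' variance-scaling route rescales the pilot's estimated RD variance by the
#' harmonic mean of the pilot arm sizes,
#' \eqn{\sigma^2_{tot} = \widehat{Var}(\hat{RD}) \cdot 2 / (1/n_0 + 1/n_1)},
#' exact when the two arms contribute equal per-arm variance and an
#' approximation otherwise.
#'
#' @param estimates An [effect_estimates()] object from the pilot analysis.
#' @param n0,n1 Pilot per-arm sizes (control, treatment); default to those
#'   recorded in `estimates`.
#' @param route `"auto"` (binomial for the binary methods, variance scaling
#'   for the augmented), `"binomial"`, or `"var_rd"`.
#' @return A single positive `sigma2_tot`.
#' @export
pilot_variance <- function(estimates, n0 = estimates$n0, n1 = estimates$n1,
                           route = c("auto", "binomial", "var_rd")) {
  stopifnot(inherits(estimates, "effect_estimates"), n0 > 0, n1 > 0)
  route <- match.arg(route)
  if (route == "auto")
    route <- if (estimates$method == "augmented") "var_rd" else "binomial"
  if (route == "binomial") {
    p0 <- estimates$p0; p1 <- estimates$p1
    return(p0 * (1 - p0) + p1 * (1 - p1))
  }
  if (is.null(estimates$var_rd) || !is.finite(estimates$var_rd) ||
      estimates$var_rd <= 0)
    stop("var_rd must be present and positive for the variance-scaling route")
  estimates$var_rd * 2 / (1 / n0 + 1 / n1)
}

#' Power curve and required sample sizes for both analysis routes
#'
#' @param delta Anticipated risk difference.
#' @param sigma2_tot_aug,sigma2_tot_bin Variance components for the
#'   augmented and binary routes.
#' @param alpha One-sided significance level.
#' @param target_power Target power.
#' @param n_grid Increasing grid of per-arm sizes to tabulate (defaults to a
#'   grid spanning both required sizes).
#' @return An object of class `sample_size_result`: `delta`, `alpha`,
#'   `target_power`, the two variance components, `n_required_aug`,
#'   `n_required_bin`, and `power_curve` (data frame of `n`, `power_aug`,
#'   `power_bin`).
#' @export
power_curve <- function(delta, sigma2_tot_aug, sigma2_tot_bin,
                        alpha = 0.05, target_power = 0.8, n_grid = NULL) {
  n_aug <- required_n(delta, sigma2_tot_aug, alpha, target_power)
  n_bin <- required_n(delta, sigma2_tot_bin, alpha, target_power)
  if (is.null(n_grid)) {
    top <- max(n_aug, n_bin)
    n_grid <- unique(round(seq(2L, ceiling(1.25 * top), length.out = 100L)))
  }
  n_grid <- as.integer(n_grid)
  if (length(n_grid) == 0L || is.unsorted(n_grid, strictly = TRUE))
    stop("n_grid must be non-empty and strictly increasing")
  curve <- data.frame(
    n = n_grid,
    power_aug = power_rd(n_grid, delta, sigma2_tot_aug, alpha),
    power_bin = power_rd(n_grid, delta, sigma2_tot_bin, alpha))
  structure(list(delta = delta, alpha = alpha, target_power = target_power,
                 sigma2_tot_aug = sigma2_tot_aug,
                 sigma2_tot_bin = sigma2_tot_bin,
                 n_required_aug = n_aug, n_required_bin = n_bin,
                 power_curve = curve),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("Sample size for one-sided alpha %.3g, target power %.0f%%, delta %.4g\n",
              x$alpha, 100 * x$target_power, x$delta))
  cat(sprintf("  augmented route: sigma2_tot %.5g -> n = %d per arm\n",
              x$sigma2_tot_aug, x$n_required_aug))
  cat(sprintf("  binary route:    sigma2_tot %.5g -> n = %d per arm\n",
              x$sigma2_tot_bin, x$n_required_bin))
  invisible(x)
}
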