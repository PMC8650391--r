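# Deterministic low-dimensional multivariate-normal probabilities.
#
# The responder region of the latent model is an axis-aligned box in at most
# three dimensions (two continuous components plus one latent binary
# component), so all probabilities reduce to uni-, bi- or tri-variate normal
# rectangle probabilities.  These are computed deterministically: the
# bivariate CDF by Drezner-Wesolowsky/Genz quadrature on the arcsine
# transform, the trivariate CDF by Gauss-Legendre integration of the
# conditional bivariate CDF.  No Monte Carlo is used in the production path.

# Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch; cached.
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- rev(e$values)
  w <- 2 * rev(e$vectors[1L, ]^2)
  out <- list(nodes = x, weights = w)
  .gl_cache[[key]] <- out
  out
}

# Gauss-Legendre order for the bivariate kernel, per Genz's schedule:
# fewer points suffice at small |rho|.
.bvn_gl <- function(rho) {
  gauss_legendre(if (abs(rho) < 0.3) 6L else if (abs(rho) < 0.75) 12L else 20L)
}

#' Bivariate standard normal CDF
#'
#' Computes \eqn{P(X \le h, Y \le k)} for standard bivariate normal
#' \eqn{(X, Y)} with correlation `rho`.  `h` and `k` are vectorised
#' (recycled against each other); `rho` is a scalar.  Accuracy is at the
#' level of double precision for \eqn{|\rho| \le 0.925} (Drezner-Wesolowsky
#' quadrature on the arcsine transform) and better than 1e-12 for larger
#' correlations (adaptive conditioning integral).
#'
#' @param h,k Upper limits; may be `-Inf`/`Inf`.
#' @param rho Scalar correlation in `(-1, 1)`; the boundary values are
#'   handled as the degenerate limits.
#' @return Vector of probabilities in `[0, 1]`.
#' @export
pbvnorm <- function(h, k, rho) {
  stopifnot(length(rho) == 1L, is.finite(rho) || abs(rho) == 1)
  nn <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), nn)
  k <- rep_len(as.numeric(k), nn)
  if (abs(rho) >= 1) {
    # degenerate limits: Y = +/- X a.s.
    if (rho >= 1) return(stats::pnorm(pmin(h, k)))
    return(pmax(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  }
  out <- numeric(nn)
  fin <- is.finite(h) & is.finite(k)
  # one or both limits infinite: reduce dimension
  out[h == -Inf | k == -Inf] <- 0
  hi <- h == Inf & k > -Inf
  out[hi] <- stats::pnorm(k[hi])
  ki <- k == Inf & h > -Inf & h < Inf
  out[ki] <- stats::pnorm(h[ki])
  if (any(fin)) {
    if (abs(rho) <= 0.925) {
      out[fin] <- .pbvnorm_drezner(h[fin], k[fin], rho)
    } else {
      out[fin] <- vapply(which(fin), function(i) .pbvnorm_cond1(h[i], k[i], rho),
                         numeric(1))
    }
  }
  pmin(1, pmax(0, out))
}

# Drezner-Wesolowsky: Phi2(h,k;rho) = Phi(h)Phi(k) +
#   1/(2*pi) * int_0^asin(rho) exp(-(h^2 - 2*h*k*sin(t) + k^2)/(2*cos(t)^2)) dt
# Vectorised over (h, k); 20-point Gauss-Legendre, near machine accuracy for
# |rho| <= 0.925.
.pbvnorm_drezner <- function(h, k, rho) {
  gl <- .bvn_gl(rho)
  asr <- asin(rho)
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (asr == 0) return(base)
  hs <- (h * h + k * k) / 2
  hk <- h * k
  acc <- 0
  for (j in seq_along(gl$nodes)) {
    sn <- sin(asr * (gl$nodes[j] + 1) / 2)
    acc <- acc + gl$weights[j] * exp((sn * hk - hs) / (1 - sn * sn))
  }
  base + acc * asr / (4 * pi)
}

# High-|rho| fallback: Phi2(h,k;rho) = int_{-inf}^{h} phi(x) Phi((k - rho x)/s) dx
# by adaptive quadrature after the substitution p = Phi(x).
.pbvnorm_cond1 <- function(h, k, rho) {
  s <- sqrt((1 - rho) * (1 + rho))
  f <- function(p) stats::pnorm((k - rho * stats::qnorm(p)) / s)
  ph <- stats::pnorm(h)
  if (ph <= 0) return(0)
  stats::integrate(f, 0, ph, rel.tol = 1e-12, abs.tol = 1e-14,
                   subdivisions = 400L)$value
}

#' Trivariate standard normal CDF
#'
#' Computes \eqn{P(X_1 \le b_1, X_2 \le b_2, X_3 \le b_3)} for a standard
#' trivariate normal with correlation matrix `R`, by Gauss-Legendre
#' integration of the conditional bivariate CDF given the third coordinate.
#' `b1` and `b2` are vectorised; `b3` and `R` are fixed.  This layout matches
#' the responder-probability computation, where the latent binary threshold
#' is common to all subjects while the continuous limits vary with baseline.
#'
#' @param b1,b2 Vectorised upper limits for the first two coordinates.
#' @param b3 Scalar upper limit for the third coordinate.
#' @param R 3x3 correlation matrix (unit diagonal, positive definite).
#' @param nodes Number of Gauss-Legendre nodes per panel (two panels used).
#' @return Vector of probabilities.
#' @export
ptvnorm <- function(b1, b2, b3, R, nodes = 24L) {
  stopifnot(is.matrix(R), nrow(R) == 3L, ncol(R) == 3L)
  nn <- max(length(b1), length(b2))
  b1 <- rep_len(as.numeric(b1), nn)
  b2 <- rep_len(as.numeric(b2), nn)
  if (!is.finite(b3)) {
    if (b3 == -Inf) return(numeric(nn))
    return(pbvnorm(b1, b2, R[1L, 2L]))
  }
  r13 <- R[1L, 3L]; r23 <- R[2L, 3L]; r12 <- R[1L, 2L]
  s13 <- sqrt(1 - r13^2); s23 <- sqrt(1 - r23^2)
  r12.3 <- (r12 - r13 * r23) / (s13 * s23)
  r12.3 <- max(-1, min(1, r12.3))
  lo <- -8.5
  hi <- min(b3, 8.5)
  if (hi <= lo) return(numeric(nn))
  out <- numeric(nn)
  mid <- (lo + hi) / 2
  gl <- gauss_legendre(nodes)
  for (panel in list(c(lo, mid), c(mid, hi))) {
    half <- (panel[2] - panel[1]) / 2
    ctr <- (panel[1] + panel[2]) / 2
    t <- ctr + half * gl$nodes
    wt <- half * gl$weights * stats::dnorm(t)
    for (j in seq_along(t)) {
      a1 <- (b1 - r13 * t[j]) / s13
      a2 <- (b2 - r23 * t[j]) / s23
      out <- out + wt[j] * pbvnorm(a1, a2, r12.3)
    }
  }
  pmin(1, pmax(0, out))
}

# CDF of a standard MVN at (possibly infinite) upper limits, dim <= 3.
.pmvnorm_upper <- function(b, R) {
  if (any(b == -Inf)) return(0)
  keep <- is.finite(b)
  d <- sum(keep)
  if (d == 0L) return(1)
  b <- b[keep]
  R <- R[keep, keep, drop = FALSE]
  if (d == 1L) return(stats::pnorm(b))
  if (d == 2L) return(pbvnorm(b[1], b[2], R[1, 2]))
  ptvnorm(b[1], b[2], b[3], R)
}

#' Multivariate normal box probability (dimension at most 3)
#'
#' Computes \eqn{P(\mathrm{lower} < Z \le \mathrm{upper})} for
#' \eqn{Z \sim N(\mathrm{mean}, \mathrm{cov})} by inclusion-exclusion over
#' the box corners after standardisation.  Deterministic, with absolute
#' accuracy around 1e-8 or better.
#'
#' @param lower,upper Numeric vectors of bounds; `-Inf`/`Inf` allowed.
#' @param mean Mean vector (default zero).
#' @param cov Covariance matrix (default identity); must be positive
#'   definite.
#' @return A single probability in `[0, 1]`.
#' @examples
#' mvn_box_prob(rep(-Inf, 3), rep(0, 3))  # 0.125
#' @export
mvn_box_prob <- function(lower, upper, mean = rep(0, length(lower)),
                         cov = diag(length(lower))) {
  d <- length(lower)
  if (d > 3L)
    stop("mvn_box_prob supports dimension <= 3, got ", d)
  stopifnot(length(upper) == d, length(mean) == d,
            is.matrix(cov), all(dim(cov) == d))
  if (any(lower >= upper))
    stop("lower bounds must be strictly below upper bounds")
  sd <- sqrt(diag(cov))
  if (any(!is.finite(sd)) || any(sd <= 0))
    stop("covariance must have positive diagonal")
  R <- cov / tcrossprod(sd)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12)
    stop("covariance/correlation matrix is not positive definite")
  lo <- (lower - mean) / sd
  up <- (upper - mean) / sd
  if (d == 1L) return(stats::pnorm(up) - stats::pnorm(lo))
  # inclusion-exclusion over corners
  total <- 0
  for (mask in 0:(2^d - 1L)) {
    pick <- as.logical(bitwAnd(mask, 2^(seq_len(d) - 1L)))
    corner <- ifelse(pick, lo, up)
    total <- total + (-1)^sum(pick) * .pmvnorm_upper(corner, R)
  }
  min(1, max(0, total))
}
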