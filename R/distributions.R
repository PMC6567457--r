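# Circular (von Mises) density, CDF and sampler, used by the HMM emissions
# and the synthetic generator.  besselI comes from base R.

#' Von Mises density
#'
#' @param x angles in radians.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0; 0 is the circular uniform).
#' @export
dvonmises <- function(x, mu = 0, kappa = 1) {
  # exponentially scaled Bessel keeps this finite for large kappa
  exp(kappa * (cos(x - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Von Mises CDF on (-pi, pi]
#'
#' Numerical (trapezoid) integration of the density from -pi; adequate for
#' probability-integral-transform residuals.
#'
#' @inheritParams dvonmises
#' @param n_grid grid resolution.
#' @export
pvonmises <- function(x, mu = 0, kappa = 1, n_grid = 4096) {
  grid <- seq(-pi, pi, length.out = n_grid)
  dens <- dvonmises(grid, mu, kappa)
  cdf <- c(0, cumsum((dens[-1] + dens[-n_grid]) / 2 * diff(grid)))
  cdf <- cdf / cdf[n_grid]
  stats::approx(grid, cdf, xout = x, rule = 2)$y
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; for very small kappa draws from the
#' circular uniform.
#'
#' @param n sample size.
#' @inheritParams dvonmises
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-7) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f))) + mu
      i <- i + 1L
    }
  }
  # wrap to (-pi, pi]
  -((-out + pi) %% (2 * pi) - pi)
}

# gamma parameterized by mean/sd (the movement-ecology convention)
.gamma_shape <- function(mean, sd) (mean / sd)^2
.gamma_rate  <- function(mean, sd) mean / sd^2

#' Jarque-Bera normality test
#'
#' `JB = n/6 * (S^2 + (K - 3)^2 / 4)` with skewness `S` and kurtosis `K`,
#' compared to a chi-square with 2 degrees of freedom.
#'
#' @param x numeric sample.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
jarque_bera <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("need at least 4 finite observations")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  S <- mean((x - m)^3) / s2^1.5
  K <- mean((x - m)^4) / s2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = jb, df = 2,
       p.value = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}
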