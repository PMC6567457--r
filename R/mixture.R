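#' Two-component univariate normal mixture by EM
#'
#' Fits `w * N(m1, s1) + (1 - w) * N(m2, s2)` by expectation-maximization
#' with multiple random restarts, returning components ordered by
#' ascending mean.  Used to set hidden-Markov-model starting values from
#' pooled step lengths and to place the first-passage-time threshold
#' between the two modes of log first-passage time.
#'
#' @param x numeric sample (n >= 10).
#' @param k number of components (only 2 supported).
#' @param max_iter EM iteration cap (default 2000; convergence is slow
#'   on unimodal data where the likelihood surface is nearly flat).
#' @param tol relative convergence tolerance on the log-likelihood
#'   (default 1e-8).
#' @param n_starts random restarts (default 10).
#' @param seed integer seed for the restarts.
#' @return object of class `gauss_mix`: list with `weights`, `means`,
#'   `sds`, `loglik`, `n`, `posterior` (n x 2), `converged`.
#' @export
fit_gauss_mixture <- function(x, k = 2, max_iter = 2000, tol = 1e-8,
                              n_starts = 10, seed = 1) {
  stopifnot(k == 2L)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10) stop("need at least 10 observations")
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    # initialize from a random split around quantiles
    q <- sort(stats::runif(1, 0.2, 0.8))
    cut <- stats::quantile(x, q)
    g <- x > cut
    if (sum(g) < 2 || sum(!g) < 2) g <- x > stats::median(x)
    mu <- c(mean(x[!g]), mean(x[g]))
    sd0 <- pmax(c(stats::sd(x[!g]), stats::sd(x[g])), 1e-6)
    w <- mean(g); w <- c(1 - w, w)
    ll_old <- -Inf; ok <- FALSE
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * stats::dnorm(x, mu[1], sd0[1])
      d2 <- w[2] * stats::dnorm(x, mu[2], sd0[2])
      tot <- d1 + d2
      if (any(tot == 0) || anyNA(tot)) break
      ll <- sum(log(tot))
      p1 <- d1 / tot
      w <- c(mean(p1), 1 - mean(p1))
      if (min(w) < 1e-8) break                    # degenerate weight
      mu <- c(sum(p1 * x) / sum(p1), sum((1 - p1) * x) / sum(1 - p1))
      sd0 <- sqrt(c(sum(p1 * (x - mu[1])^2) / sum(p1),
                    sum((1 - p1) * (x - mu[2])^2) / sum(1 - p1)))
      if (any(sd0 < 1e-8)) break                  # degenerate sd -> restart
      if (abs(ll - ll_old) < tol * (abs(ll) + 1)) { ok <- TRUE; break }
      ll_old <- ll
    }
    if (!ok) next
    if (is.null(best) || ll > best$loglik) {
      o <- order(mu)
      d1 <- w[o[1]] * stats::dnorm(x, mu[o[1]], sd0[o[1]])
      d2 <- w[o[2]] * stats::dnorm(x, mu[o[2]], sd0[o[2]])
      best <- structure(list(weights = w[o], means = mu[o], sds = sd0[o],
                             loglik = ll, n = n,
                             posterior = cbind(d1, d2) / (d1 + d2),
                             converged = TRUE),
                        class = "gauss_mix")
    }
  }
  if (is.null(best))
    stop("mixture EM failed to converge from any restart (degenerate data?)")
  best
}

#' @export
print.gauss_mix <- function(x, ...) {
  cat(sprintf(
    "<gauss_mix> 2 components (n = %d, loglik = %.2f)\n", x$n, x$loglik))
  print(data.frame(weight = x$weights, mean = x$means, sd = x$sds))
  invisible(x)
}

#' @export
logLik.gauss_mix <- function(object, ...) {
  structure(object$loglik, df = 5L, nobs = object$n, class = "logLik")
}

#' Is a fitted two-component mixture bimodal?
#'
#' The two modes are considered separated when the means differ by more
#' than one pooled standard deviation.
#'
#' @param mix a `gauss_mix`.
#' @export
is_bimodal <- function(mix) {
  pooled <- sqrt(sum(mix$weights * mix$sds^2))
  diff(mix$means) > pooled
}
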