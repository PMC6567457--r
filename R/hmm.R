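# Two-state (n-state capable) hidden Markov model on step length and
# signed turn angle: gamma step-length emissions, von Mises turn-angle
# emissions, forward-likelihood maximization, Viterbi decoding, and
# one-step-ahead pseudo-residual diagnostics.

# assemble concatenated step/turn vectors + sequence starts from one or
# more step tables (each from compute_steps on a regularized trip; a
# `block` column, if present, further splits sequences at long gaps)
.hmm_data <- function(steps) {
  if (is.data.frame(steps)) steps <- list(steps)
  step <- numeric(); turn <- numeric(); starts <- integer()
  for (s in steps) {
    starts <- c(starts, length(step) + 1L)
    if (!is.null(s$block) && length(unique(s$block)) > 1L) {
      b <- s$block
      starts <- c(starts, length(step) + which(diff(b) != 0) + 1L)
    }
    step <- c(step, s$step_length)
    turn <- c(turn, s$turn_signed)
  }
  # zero steps break gamma support; displace to half the smallest positive
  pos <- step[step > 0 & is.finite(step)]
  if (any(step == 0, na.rm = TRUE))
    step[!is.na(step) & step == 0] <- min(pos) / 2
  list(step = step, turn = turn, starts = starts, n = length(step))
}

# emission probability matrix (n x k); NA observations contribute 1
.hmm_emissions <- function(dat, step_mean, step_sd, kappa) {
  k <- length(step_mean)
  e <- matrix(1, dat$n, k)
  so <- !is.na(dat$step); to <- !is.na(dat$turn)
  for (j in seq_len(k)) {
    ej <- rep(1, dat$n)
    ej[so] <- suppressWarnings(
      stats::dgamma(dat$step[so], shape = .gamma_shape(step_mean[j], step_sd[j]),
                    rate = .gamma_rate(step_mean[j], step_sd[j])))
    ej[to] <- ej[to] * dvonmises(dat$turn[to], 0, kappa[j])
    ej[!is.finite(ej)] <- 1e-300
    e[, j] <- pmax(ej, 1e-300)
  }
  e
}

.stationary <- function(trans) {
  k <- nrow(trans)
  A <- rbind(t(diag(k) - trans), rep(1, k))
  b <- c(rep(0, k), 1)
  sol <- stats::lm.fit(A, b)$coefficients
  p <- pmax(sol, 1e-12)
  p / sum(p)
}

.par_pack <- function(step_mean, step_sd, kappa, trans) {
  k <- length(step_mean)
  off <- log(trans / diag(trans))[row(trans) != col(trans)]
  c(log(step_mean), log(step_sd), log(kappa), off)
}

.par_unpack <- function(par, k) {
  step_mean <- exp(par[1:k])
  step_sd <- exp(par[k + 1:k])
  kappa <- exp(par[2 * k + 1:k])
  off <- par[3 * k + seq_len(k * (k - 1))]
  trans <- diag(k)
  trans[row(trans) != col(trans)] <- exp(off)
  trans <- trans / rowSums(trans)
  list(step_mean = step_mean, step_sd = step_sd, kappa = kappa,
       trans = trans)
}

#' Simulate step metrics from a hidden Markov model
#'
#' Draws a state path from the Markov chain (started from its stationary
#' distribution) and emits gamma step lengths and von Mises signed turn
#' angles, in the same table layout as [compute_steps()].
#'
#' @param step_mean,step_sd per-state gamma step-length mean/SD, m.
#' @param kappa per-state von Mises turn concentration.
#' @param trans row-stochastic transition matrix.
#' @param n number of locations.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return list: `steps` (a step table usable by [hmm_fit()]) and
#'   `states` (true state indices).
#' @export
hmm_simulate <- function(step_mean, step_sd, kappa, trans, n,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(step_mean)
  states <- integer(n)
  states[1] <- sample.int(k, 1, prob = .stationary(trans))
  for (t in 2:n)
    states[t] <- sample.int(k, 1, prob = trans[states[t - 1], ])
  step <- stats::rgamma(n, shape = .gamma_shape(step_mean[states],
                                                step_sd[states]),
                        rate = .gamma_rate(step_mean[states],
                                           step_sd[states]))
  turn <- vapply(seq_len(n), function(t) rvonmises(1, 0, kappa[states[t]]),
                 numeric(1))
  steps <- data.frame(time = seq_len(n), step_length = step,
                      speed = step / 15, turn_signed = turn,
                      turn_abs = abs(turn) * 180 / pi)
  steps$step_length[1] <- NA; steps$speed[1] <- NA
  steps$turn_signed[c(1, n)] <- NA; steps$turn_abs[c(1, n)] <- NA
  list(steps = steps, states = states)
}

#' Starting values for the hidden Markov model
#'
#' Fits a two-component normal mixture to pooled step lengths; the
#' component means/SDs become the per-state initial gamma parameters
#' (state 1 = smaller mean).  Turn-angle concentrations start at 0.1
#' (near-uniform) with mean 0.  Unimodal step data fall back to a
#' 30th/70th-percentile split with a warning.
#'
#' @param step_lengths pooled step lengths, m (n >= 100).
#' @param seed integer seed for the mixture restarts.
#' @return list of class `hmm_init`: `step_mean`, `step_sd`, `kappa`.
#' @export
hmm_init <- function(step_lengths, seed = 1) {
  x <- step_lengths[is.finite(step_lengths) & step_lengths > 0]
  if (length(x) < 100) stop("need at least 100 steps")
  mix <- try(fit_gauss_mixture(x, seed = seed), silent = TRUE)
  if (inherits(mix, "try-error") || !is_bimodal(mix)) {
    warning("step lengths look unimodal; quantile-split starting values")
    lo <- x[x <= stats::quantile(x, 0.3)]
    hi <- x[x >= stats::quantile(x, 0.7)]
    mm <- c(mean(lo), mean(hi)); ss <- pmax(c(stats::sd(lo), stats::sd(hi)),
                                            1e-3)
  } else {
    mm <- mix$means; ss <- mix$sds
  }
  structure(list(step_mean = mm, step_sd = ss, kappa = c(0.1, 0.1)),
            class = "hmm_init")
}

#' Fit a hidden Markov model to step metrics
#'
#' Maximizes the forward-algorithm joint likelihood of gamma step-length
#' and von Mises turn-angle emissions (turn means fixed at 0) over the
#' emission parameters and transition matrix by quasi-Newton search on
#' transformed parameters.  Sequences (trips, and blocks within trips
#' separated by long gaps) are treated as independent, each starting from
#' the stationary distribution of the transition matrix.  Data should be
#' regularly sampled (see [regularize()]); turn angles are signed.
#'
#' @param steps a [compute_steps()] table or list of them (one per trip).
#' @param init an [hmm_init()], or `NULL` to compute one from the data.
#' @param n_states number of states (default 2).
#' @param max_iter optimizer iteration cap.
#' @param seed integer seed (used only if `init` is `NULL`).
#' @return object of class `hmm_model`.
#' @export
hmm_fit <- function(steps, init = NULL, n_states = 2, max_iter = 500,
                    seed = 1) {
  dat <- .hmm_data(steps)
  k <- n_states
  if (is.null(init)) init <- hmm_init(dat$step, seed = seed)
  if (k == 2L) {
    step_mean <- init$step_mean; step_sd <- init$step_sd
    kappa <- init$kappa
  } else {
    qs <- stats::quantile(dat$step, probs = (seq_len(k) - 0.5) / k,
                          na.rm = TRUE)
    step_mean <- as.numeric(qs)
    step_sd <- rep(stats::sd(dat$step, na.rm = TRUE) / k, k)
    kappa <- rep(0.1, k)
  }
  trans0 <- matrix(0.05 / (k - 1), k, k); diag(trans0) <- 0.95
  par0 <- .par_pack(step_mean, step_sd, kappa, trans0)
  negll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 50)) return(1e10)
    p <- .par_unpack(par, k)
    if (any(!is.finite(unlist(p)))) return(1e10)
    e <- .hmm_emissions(dat, p$step_mean, p$step_sd, p$kappa)
    v <- .hmm_forward_loglik(e, p$trans, .stationary(p$trans), dat$starts)
    if (!is.finite(v)) return(1e10)
    -v
  }
  ll0 <- -negll(par0)
  if (!is.finite(ll0)) stop("non-finite likelihood at starting values")
  opt <- stats::optim(par0, negll, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-10))
  p <- .par_unpack(opt$par, k)
  ll <- -opt$value
  if (!is.finite(ll)) stop("non-finite likelihood at optimum")
  # order states by ascending step-length mean
  o <- order(p$step_mean)
  model <- structure(list(
    n_states = k,
    step_mean = p$step_mean[o], step_sd = p$step_sd[o],
    kappa = p$kappa[o],
    trans = p$trans[o, o, drop = FALSE],
    init_probs = .stationary(p$trans)[o],
    loglik = ll, loglik_start = ll0, n = dat$n,
    convergence = opt$convergence), class = "hmm_model")
  if (max(model$trans[row(model$trans) != col(model$trans)]) < 1e-4)
    warning("transition matrix is near-degenerate (single-state data?)")
  model
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> %d states, n = %d, loglik = %.2f\n",
              x$n_states, x$n, x$loglik))
  print(data.frame(step_mean = x$step_mean, step_sd = x$step_sd,
                   turn_kappa = x$kappa))
  cat("transition matrix:\n"); print(round(x$trans, 4))
  invisible(x)
}

#' @export
logLik.hmm_model <- function(object, ...) {
  k <- object$n_states
  structure(object$loglik, df = 3L * k + k * (k - 1L), nobs = object$n,
            class = "logLik")
}

#' @export
coef.hmm_model <- function(object, ...) {
  list(step_mean = object$step_mean, step_sd = object$step_sd,
       turn_kappa = object$kappa, trans = object$trans)
}

#' Decode behavioral states from a fitted HMM
#'
#' Global (Viterbi) decoding by default; posterior (local) decoding via
#' `method = "posterior"`.  The state with the smaller step-length mean
#' (slow, tortuous movement) is labeled foraging; with more than two
#' states every non-foraging state maps to commuting.  No location is
#' omitted.
#'
#' @param model an [hmm_fit()] result.
#' @param steps the same step table(s) used for fitting (or new data).
#' @param method `"viterbi"` or `"posterior"`.
#' @return a [state_seq()] (attribute `state_index` keeps the raw
#'   decoded state numbers).
#' @export
hmm_decode <- function(model, steps, method = c("viterbi", "posterior")) {
  method <- match.arg(method)
  dat <- .hmm_data(steps)
  e <- .hmm_emissions(dat, model$step_mean, model$step_sd, model$kappa)
  if (method == "viterbi") {
    idx <- .hmm_viterbi(e, model$trans, model$init_probs, dat$starts)
  } else {
    idx <- apply(.hmm_posterior(e, model, dat), 1, which.max)
  }
  lab <- ifelse(idx == 1L, "foraging", "commuting")
  out <- state_seq(lab)
  attr(out, "state_index") <- idx
  out
}

# forward-backward posterior (R implementation; posterior decoding is a
# diagnostic path, speed is not critical)
.hmm_posterior <- function(e, model, dat) {
  n <- dat$n; k <- model$n_states
  post <- matrix(0, n, k)
  bounds <- c(dat$starts, n + 1L)
  for (s in seq_along(dat$starts)) {
    rng <- bounds[s]:(bounds[s + 1L] - 1L)
    m <- length(rng)
    al <- matrix(0, m, k); be <- matrix(0, m, k)
    phi <- model$init_probs * e[rng[1], ]
    al[1, ] <- phi / sum(phi)
    for (t in seq_len(m - 1)) {
      phi <- (al[t, ] %*% model$trans) * e[rng[t + 1], ]
      al[t + 1, ] <- phi / sum(phi)
    }
    be[m, ] <- 1
    for (t in rev(seq_len(m - 1))) {
      v <- model$trans %*% (e[rng[t + 1], ] * be[t + 1, ])
      be[t, ] <- v / sum(v)
    }
    pr <- al * be
    post[rng, ] <- pr / rowSums(pr)
  }
  post
}

#' One-step-ahead pseudo-residuals and normality diagnostics
#'
#' Probability-integral-transform residuals of each emission stream under
#' the one-step-ahead predictive distribution, mapped through the
#' standard-normal quantile, with a Jarque-Bera normality test per
#' stream.  Probabilities of exactly 0 or 1 are clipped with a warning.
#'
#' @param model an [hmm_fit()] result.
#' @param steps the step table(s).
#' @return list: `step_resid`, `turn_resid` (z-scores, `NA` where the
#'   observation is missing), `jb_step`, `jb_turn` ([jarque_bera()]
#'   results).
#' @export
hmm_pseudo_residuals <- function(model, steps) {
  dat <- .hmm_data(steps)
  e <- .hmm_emissions(dat, model$step_mean, model$step_sd, model$kappa)
  w <- .hmm_predictive(e, model$trans, model$init_probs, dat$starts)
  k <- model$n_states
  u_step <- rep(NA_real_, dat$n); u_turn <- rep(NA_real_, dat$n)
  so <- !is.na(dat$step); to <- !is.na(dat$turn)
  for (j in seq_len(k)) {
    ps <- stats::pgamma(dat$step[so],
                        shape = .gamma_shape(model$step_mean[j], model$step_sd[j]),
                        rate = .gamma_rate(model$step_mean[j], model$step_sd[j]))
    u_step[so] <- if (j == 1) w[so, j] * ps else u_step[so] + w[so, j] * ps
    pt <- pvonmises(dat$turn[to], 0, model$kappa[j])
    u_turn[to] <- if (j == 1) w[to, j] * pt else u_turn[to] + w[to, j] * pt
  }
  clip <- function(u) {
    bad <- !is.na(u) & (u <= 0 | u >= 1)
    if (any(bad)) {
      warning(sum(bad), " residual probabilities clipped away from 0/1")
      u[bad] <- pmin(pmax(u[bad], 1e-10), 1 - 1e-10)
    }
    u
  }
  zs <- stats::qnorm(clip(u_step)); zt <- stats::qnorm(clip(u_turn))
  list(step_resid = zs, turn_resid = zt,
       jb_step = jarque_bera(zs), jb_turn = jarque_bera(zt))
}

#' Sensitivity of HMM accuracy to GPS sampling interval
#'
#' Subsamples each trip to every candidate interval, regularizes, refits
#' the pooled two-state model, decodes, scores balanced accuracy against
#' the buzz-positive fixes reassigned at that interval, and regresses the
#' per-interval median balanced accuracy on the interval by ordinary
#' least squares.
#'
#' @param trips list of [bat_trip()]s at the nominal interval.
#' @param buzz_times_list list of numeric buzz-time vectors, one per trip.
#' @param intervals candidate intervals, s (multiples of the nominal dt).
#' @param seed integer seed.
#' @param min_locations trips shorter than this at an interval are
#'   skipped (default 50).
#' @return list: `table` (`data.frame` of interval and median balanced
#'   accuracy), `slope` (OLS slope per second), `fit` (the `lm`).
#' @export
hmm_subsampling_experiment <- function(trips, buzz_times_list, intervals,
                                       seed = 1, min_locations = 50) {
  rows <- lapply(intervals, function(iv) {
    sub <- lapply(trips, subsample, interval = iv)
    keep <- vapply(sub, nrow, 1L) >= min_locations
    if (!any(keep)) return(NULL)
    sub <- sub[keep]
    steps <- lapply(sub, function(tr) compute_steps(regularize(tr, dt = iv)))
    model <- hmm_fit(steps, seed = seed)
    ba <- vapply(seq_along(sub), function(i) {
      st <- hmm_decode(model, steps[[i]])
      bz <- assign_buzzes_to_fixes(
        data.frame(time = buzz_times_list[keep][[i]]), sub[[i]],
        max_outside = iv)
      sc <- score_trip(st, buzz_fixes(bz))
      sc$balanced_accuracy
    }, numeric(1))
    data.frame(interval = iv, median_ba = stats::median(ba, na.rm = TRUE))
  })
  tab <- do.call(rbind, rows)
  fit <- stats::lm(median_ba ~ interval, data = tab)
  list(table = tab, slope = unname(stats::coef(fit)[2]), fit = fit)
}
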