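# Correlated-velocity movement (CVM): Ornstein-Uhlenbeck velocity models,
# exact simulation, likelihood fitting on finite-difference velocities,
# sliding-window change-point scanning, BIC thinning, and segment
# classification (unbiased CVM = foraging, advective CVM = commuting).

# Moments of the time-averaged OU velocity observed as finite differences
# of position over intervals of length dt.  With u = dt / tau:
#   per-coordinate variance = (nu^2 / 2) * psi(u)
#   lag-1 autocorrelation    = rho(u)
.cvm_psi <- function(u) ifelse(u < 1e-6, 1 - u / 3,
                               2 * (u - 1 + exp(-u)) / u^2)
.cvm_rho <- function(u) ifelse(u < 1e-6, (1 - 2 * u / 3) / (1 - u / 3),
                               (1 - exp(-u))^2 / (2 * (u - 1 + exp(-u))))

#' Simulate a correlated-velocity movement track
#'
#' Velocities follow a per-coordinate Ornstein-Uhlenbeck process with
#' relaxation time `tau`, mean (advective) velocity `mu`, and stationary
#' per-coordinate variance `nu^2 / 2`, so the stationary root-mean-square
#' speed of the random component is `nu`.  Positions are the exact
#' integral of the velocity process: each step samples the joint Gaussian
#' transition of (position, velocity), with no Euler discretization
#' error.
#'
#' @param nu RMS speed of the random velocity component, m/s.
#' @param tau velocity autocorrelation timescale, s.
#' @param mu advective velocity, length-2 (m/s); `c(0, 0)` is the
#'   unbiased model.
#' @param dt sampling interval, s.
#' @param n number of locations.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @param trip_id identifier.
#' @return a [bat_trip()]; the instantaneous velocities at fix times are
#'   attached as attribute `"velocity"` (n x 2).
#' @export
simulate_cvm <- function(nu, tau, mu = c(0, 0), dt = 15, n = 200,
                         seed = NULL, trip_id = "cvm") {
  stopifnot(nu > 0, tau > 0, dt > 0, n >= 2)
  if (!is.null(seed)) set.seed(seed)
  s2 <- nu^2 / 2                      # stationary per-coordinate variance
  ed <- exp(-dt / tau)
  # joint transition covariance of (integrated displacement, velocity)
  vxx <- s2 * tau^2 * (2 * dt / tau - 3 + 4 * ed - ed^2)
  vvv <- s2 * (1 - ed^2)
  vxv <- s2 * tau * (1 - ed)^2
  S <- matrix(c(vxx, vxv, vxv, vvv), 2, 2)
  L <- t(chol(S + diag(1e-12, 2)))
  pos <- matrix(0, n, 2); vel <- matrix(0, n, 2)
  vel[1, ] <- mu + stats::rnorm(2, 0, sqrt(s2))
  for (t in seq_len(n - 1)) {
    for (c in 1:2) {
      z <- L %*% stats::rnorm(2)
      dv <- vel[t, c] - mu[c]
      pos[t + 1, c] <- pos[t, c] + mu[c] * dt + dv * tau * (1 - ed) + z[1]
      vel[t + 1, c] <- mu[c] + dv * ed + z[2]
    }
  }
  out <- bat_trip(seq(0, by = dt, length.out = n), pos[, 1], pos[, 2],
                  trip_id = trip_id, nominal_dt = dt)
  attr(out, "velocity") <- vel
  out
}

# Exact Gaussian log-likelihood of position-differenced (time-averaged)
# OU velocities for a given tau, by Kalman filtering the instantaneous
# velocity with correlated observation/state noise.  All covariances
# scale with the stationary per-coordinate variance s2, which is
# profiled in closed form.  v is an m x 2 matrix of finite-difference
# velocities.
.cvm_profile_ll <- function(v, dt, tau, mu) {
  m <- nrow(v)
  u <- dt / tau
  e <- exp(-u)
  a <- e                              # state transition
  b <- if (u < 1e-6) 1 - u / 2 else (1 - e) / u   # obs loading on w_{i-1}
  q <- 1 - e^2                        # state noise (unit s2)
  r <- .cvm_psi(u) - b^2              # obs noise (unit s2)
  cc <- b * (1 - e)                   # cov(state noise, obs noise)
  z <- sweep(v, 2, mu)
  Q <- 0; logS <- 0
  for (coord in 1:2) {
    mm <- 0; P <- 1                   # stationary init (unit s2)
    for (i in seq_len(m)) {
      y <- z[i, coord] - b * mm
      S <- b^2 * P + r
      C <- a * b * P + cc
      Q <- Q + y^2 / S
      if (coord == 1) logS <- logS + log(S)   # S identical across coords
      mm <- a * mm + (C / S) * y
      P <- a^2 * P + q - C^2 / S
    }
  }
  M <- 2 * m
  s2 <- Q / M
  ll <- -0.5 * M * (log(2 * pi * s2) + 1) - logS
  list(ll = ll, s2 = s2, rho = .cvm_rho(u))
}

#' Fit a correlated-velocity model to a track segment
#'
#' Maximum-likelihood fit of the finite-difference velocity series under
#' the exact Gaussian law of a time-averaged Ornstein-Uhlenbeck velocity
#' (Kalman filter over the instantaneous velocity, profiled variance,
#' one-dimensional search over `tau`); position differencing biases
#' naive AR(1) estimates of both `tau` and `nu`, which this construction
#' avoids.  The unbiased model (UCVM) fixes the mean velocity at zero;
#' the advective model (ACVM) estimates it.
#'
#' @param segment a [bat_trip()] with at least 4 locations.
#' @param model `"UCVM"` or `"ACVM"`.
#' @param tau_range search bounds for `tau`, s.
#' @return list of class `cvm_fit`: `model`, `nu` (RMS speed, m/s), `tau`
#'   (s), `mu` (advective velocity), `loglik`, `bic`, `n` (velocity
#'   observations), `tau_at_bound`.
#' @export
fit_cvm <- function(segment, model = c("UCVM", "ACVM"),
                    tau_range = c(0.5, 36000)) {
  model <- match.arg(model)
  if (nrow(segment) < 4) stop("segment too short to fit (need >= 4 locations)")
  dtv <- diff(segment$time)
  dt <- stats::median(dtv)
  v <- cbind(diff(segment$x), diff(segment$y)) / dtv
  m <- nrow(v)
  mu <- if (model == "ACVM") colMeans(v) else c(0, 0)
  obj <- function(lt) -.cvm_profile_ll(v, dt, exp(lt), mu)$ll
  op <- stats::optimize(obj, log(tau_range))
  tau <- exp(op$minimum)
  pr <- .cvm_profile_ll(v, dt, tau, mu)
  nu <- sqrt(2 * pr$s2)
  kpar <- if (model == "ACVM") 4 else 2
  structure(list(model = model, nu = nu, tau = tau, mu = mu,
                 loglik = pr$ll, bic = kpar * log(m) - 2 * pr$ll, n = m,
                 tau_at_bound = min(abs(log(tau) - log(tau_range))) < 0.01),
            class = "cvm_fit")
}

#' @export
print.cvm_fit <- function(x, ...) {
  cat(sprintf("<cvm_fit> %s: nu = %.2f m/s, tau = %.1f s, |mu| = %.2f m/s, BIC = %.1f (n = %d)\n",
              x$model, x$nu, x$tau, sqrt(sum(x$mu^2)), x$bic, x$n))
  invisible(x)
}

#' Scan a trip for candidate velocity change points
#'
#' Slides a window of `window` locations down the track in steps of
#' `step` locations.  Within each window the split log-likelihood (two
#' independent unbiased CVM fits) is profiled over interior split
#' positions; each window's best split with positive gain over the
#' unsplit fit becomes a candidate.  If no window admits a fit (e.g.
#' non-convergence on very short windows), the window is enlarged to
#' `fallback_window` for that trip.
#'
#' @param trip a [bat_trip()].
#' @param window window length in locations (default 8, i.e. 2 min at
#'   15 s fixes).
#' @param step window shift in locations (default 5, i.e. 1.25 min).
#' @param min_side minimum locations on each side of a split (default 4).
#' @param fallback_window enlarged window on failure (default 10).
#' @return `data.frame` of candidates: `time` (s), `index` (location),
#'   `gain` (split log-likelihood gain).
#' @export
scan_changepoints <- function(trip, window = 8, step = 5, min_side = 4,
                              fallback_window = 10) {
  n <- nrow(trip)
  empty <- data.frame(time = numeric(), index = integer(), gain = numeric())
  if (n < window) return(empty)
  scan1 <- function(win) {
    starts <- seq(1L, n - win + 1L, by = step)
    out <- vector("list", length(starts))
    for (ii in seq_along(starts)) {
      i0 <- starts[ii]; i1 <- i0 + win - 1L
      seg <- trip[i0:i1, , drop = FALSE]
      full <- try(fit_cvm(bat_trip(seg$time, seg$x, seg$y)), silent = TRUE)
      if (inherits(full, "try-error")) return(NULL)
      best_gain <- -Inf; best_s <- NA_integer_
      for (s in (min_side):(win - min_side)) {
        a <- try(fit_cvm(bat_trip(seg$time[1:s], seg$x[1:s], seg$y[1:s])),
                 silent = TRUE)
        b <- try(fit_cvm(bat_trip(seg$time[(s + 1):win], seg$x[(s + 1):win],
                                  seg$y[(s + 1):win])), silent = TRUE)
        if (inherits(a, "try-error") || inherits(b, "try-error")) next
        g <- a$loglik + b$loglik - full$loglik
        if (g > best_gain) { best_gain <- g; best_s <- s }
      }
      if (is.finite(best_gain) && best_gain > 0)
        out[[ii]] <- data.frame(time = trip$time[i0 + best_s - 1L],
                                index = i0 + best_s - 1L, gain = best_gain)
    }
    prof <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(prof) || nrow(prof) == 0L) return(prof)
    # candidates are local maxima of the gain profile across windows
    g <- prof$gain
    keep <- rep(TRUE, length(g))
    if (length(g) > 1) {
      keep <- c(g[-length(g)] >= g[-1], TRUE) &
              c(TRUE, g[-1] > g[-length(g)])
    }
    prof[keep, , drop = FALSE]
  }
  res <- scan1(window)
  if (is.null(res) && fallback_window > window && n >= fallback_window) {
    warning("window enlarged to ", fallback_window, " locations")
    res <- scan1(fallback_window)
  }
  if (is.null(res)) return(empty)
  res[order(res$time), , drop = FALSE]
}

#' Thin candidate change points by separation and BIC support
#'
#' First enforces a minimum time separation (keeping the higher-gain
#' candidate of any conflicting pair), then prunes recursively by
#' backward elimination on the whole-track BIC: starting from all
#' candidates as segment boundaries, each boundary's support is the
#' likelihood gained by fitting its two flanking segments separately
#' (unbiased CVM each) rather than merged; the weakest boundary whose
#' gain does not cover the two extra parameters is removed, flanking
#' segments merge, and supports are recomputed until every surviving
#' boundary is BIC-supported against its full flanking context.
#' Surviving boundaries are then refined locally: the split position is
#' profiled over neighboring locations to maximize the two-segment
#' likelihood.
#'
#' @param trip the [bat_trip()] being segmented.
#' @param candidates a [scan_changepoints()] table.
#' @param min_sep minimum separation, s (default 30).
#' @param refine_span locations searched on each side when refining a
#'   surviving boundary (default 50).
#' @return list of class `changepoint_set`: `times`, `indices`,
#'   `candidates`.
#' @export
thin_changepoints <- function(trip, candidates, min_sep = 30,
                              refine_span = 50) {
  cands <- candidates
  if (nrow(cands) > 0) {
    cands <- cands[order(-cands$gain), , drop = FALSE]
    kept <- integer()
    for (r in seq_len(nrow(cands)))
      if (all(abs(cands$time[r] - cands$time[kept]) >= min_sep))
        kept <- c(kept, r)
    cands <- cands[sort(kept), , drop = FALSE]
    cands <- cands[order(cands$time), , drop = FALSE]
  }
  n <- nrow(trip)
  ll_cache <- new.env(parent = emptyenv())
  seg_ll <- function(i0, i1) {
    key <- paste0(i0, ",", i1)
    if (!is.null(ll_cache[[key]])) return(ll_cache[[key]])
    v <- fit_cvm(bat_trip(trip$time[i0:i1], trip$x[i0:i1],
                          trip$y[i0:i1]))$loglik
    ll_cache[[key]] <- v
    v
  }
  bnd <- cands$index
  bnd <- bnd[bnd >= 4L & bnd <= n - 3L]
  penalty <- 2 * log(n - 1)              # 2 params per extra segment
  while (length(bnd) > 0L) {
    edges <- c(1L, bnd, n)
    support <- vapply(seq_along(bnd), function(j) {
      i0 <- edges[j]; ic <- edges[j + 1L]; i1 <- edges[j + 2L]
      2 * (seg_ll(i0, ic) + seg_ll(ic, i1) - seg_ll(i0, i1))
    }, numeric(1))
    worst <- which.min(support)
    if (support[worst] >= penalty) break
    bnd <- bnd[-worst]
  }
  # refine each surviving boundary to the maximum-likelihood split
  # position within its flanking region (capped at refine_span fixes)
  if (length(bnd) > 0L && refine_span > 0L) {
    edges <- c(1L, bnd, n)
    for (j in seq_along(bnd)) {
      i0 <- edges[j]; i1 <- edges[j + 2L]
      lo <- max(i0 + 3L, bnd[j] - refine_span)
      hi <- min(i1 - 3L, bnd[j] + refine_span)
      if (lo > hi) next
      cand_pos <- lo:hi
      lls <- vapply(cand_pos, function(s) seg_ll(i0, s) + seg_ll(s, i1),
                    numeric(1))
      bnd[j] <- cand_pos[which.max(lls)]
      edges[j + 1L] <- bnd[j]
    }
  }
  structure(list(times = trip$time[bnd], indices = bnd,
                 candidates = candidates, min_sep = min_sep),
            class = "changepoint_set")
}

#' @export
print.changepoint_set <- function(x, ...) {
  cat(sprintf("<changepoint_set> %d accepted of %d candidate change points\n",
              length(x$times), nrow(x$candidates)))
  invisible(x)
}

#' Classify inter-change-point segments (CVCP)
#'
#' Each segment between accepted change points is fit with both the
#' unbiased and the advective CVM; the lower BIC wins.  Unbiased
#' segments (no persistent drift: area-restricted search) are labeled
#' foraging, advective segments commuting.  Segments too short to fit
#' are merged into the neighboring segment with the closer mean speed.
#' Every location is labeled (none omitted).
#'
#' @param trip a [bat_trip()].
#' @param cps a [thin_changepoints()] result (or vector of change-point
#'   location indices).
#' @return list: `states` (a [state_seq()]), `segments` (`data.frame`
#'   with `start_s`, `end_s`, `model`, `nu`, `tau`, `mu_x`, `mu_y`,
#'   `bic`).
#' @export
segment_cvcp <- function(trip, cps) {
  idx <- if (inherits(cps, "changepoint_set")) cps$indices else cps
  n <- nrow(trip)
  bounds <- unique(c(1L, sort(idx), n))
  # merge segments shorter than 4 locations into the closer-speed neighbor
  repeat {
    lens <- diff(bounds)
    short <- which(lens < 4L & lens > 0L)
    if (length(short) == 0 || length(bounds) <= 2L) break
    j <- short[1]
    mean_speed <- function(i0, i1) {
      dd <- sqrt(diff(trip$x[i0:i1])^2 + diff(trip$y[i0:i1])^2)
      sum(dd) / (trip$time[i1] - trip$time[i0])
    }
    sj <- mean_speed(bounds[j], bounds[j + 1L])
    drop_left <- if (j == 1L) FALSE
      else if (j + 1L == length(bounds)) TRUE
      else abs(mean_speed(bounds[j - 1L], bounds[j]) - sj) <=
           abs(mean_speed(bounds[j + 1L], min(bounds[j + 2L], n)) - sj)
    bounds <- bounds[-(if (drop_left) j else j + 1L)]
  }
  labels <- rep("commuting", n)
  segs <- vector("list", length(bounds) - 1L)
  for (j in seq_len(length(bounds) - 1L)) {
    i0 <- bounds[j]; i1 <- bounds[j + 1L]
    sub <- bat_trip(trip$time[i0:i1], trip$x[i0:i1], trip$y[i0:i1])
    fu <- fit_cvm(sub, "UCVM"); fa <- fit_cvm(sub, "ACVM")
    win <- if (fu$bic <= fa$bic) fu else fa
    lab <- if (win$model == "UCVM") "foraging" else "commuting"
    labels[i0:i1] <- lab
    segs[[j]] <- data.frame(start_s = trip$time[i0], end_s = trip$time[i1],
                            model = win$model, nu = win$nu, tau = win$tau,
                            mu_x = win$mu[1], mu_y = win$mu[2],
                            bic = win$bic)
  }
  list(states = state_seq(labels), segments = do.call(rbind, segs))
}

#' Full change-point segmentation pipeline for one trip
#'
#' @param trip a [bat_trip()].
#' @param window,step,min_sep see [scan_changepoints()] and
#'   [thin_changepoints()].
#' @return as [segment_cvcp()], plus `changepoints`.
#' @export
segment_cvcp_pipeline <- function(trip, window = 8, step = 5,
                                  min_sep = 30) {
  cand <- scan_changepoints(trip, window = window, step = step)
  cps <- thin_changepoints(trip, cand, min_sep = min_sep)
  out <- segment_cvcp(trip, cps)
  out$changepoints <- cps
  out
}
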