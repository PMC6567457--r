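# Shared fixtures and independent oracles used across test files.

# straight constant-velocity trip along +x
straight_trip <- function(n = 100, v = 5, dt = 15) {
  bat_trip(seq(0, by = dt, length.out = n),
           seq(0, by = v * dt, length.out = n), rep(0, n),
           trip_id = "straight", nominal_dt = dt)
}

# brute-force first-passage time on the discrete fix sequence: time to
# the first *fix* outside the circle, forward + backward (no
# interpolation); the packaged version interpolates, so values agree to
# within one fix interval on each side
fpt_oracle_discrete <- function(trip, r) {
  n <- nrow(trip)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- sqrt((trip$x - trip$x[i])^2 + (trip$y - trip$y[i])^2)
    fwd <- which(d > r & seq_len(n) > i)
    bwd <- which(d > r & seq_len(n) < i)
    if (length(fwd) && length(bwd))
      out[i] <- (trip$time[min(fwd)] - trip$time[i]) +
                (trip$time[i] - trip$time[max(bwd)])
  }
  out
}

# brute-force HMM likelihood: sum over all state paths
forward_oracle <- function(emis, trans, init) {
  n <- nrow(emis); k <- ncol(emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- init[s[1]] * emis[1, s[1]]
    if (n > 1) for (t in 2:n) p <- p * trans[s[t - 1], s[t]] * emis[t, s[t]]
    tot <- tot + p
  }
  log(tot)
}

# exact two-sided Wilcoxon signed-rank p-value by enumerating all 2^n
# sign assignments
wilcox_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mu <- sum(r) / 2
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# tie-corrected Friedman statistic from the rank formula
friedman_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- t(apply(m, 1, rank))
  stat_num <- (12 / (n * k * (k + 1))) * sum((colSums(R) - n * (k + 1) / 2)^2)
  # tie correction
  Tj <- apply(m, 1, function(row) {
    tb <- table(row); sum(tb^3 - tb)
  })
  C <- 1 - sum(Tj) / (n * k * (k^2 - 1))
  stat_num / C
}

# brute-force duty-cycle bout detection over the 10 shifts
duty_oracle <- function(buzz_times, bouts, on = 0.5, period = 5) {
  shifts <- seq(0, period - on, by = on)
  sapply(shifts, function(sh) {
    det <- 0
    for (i in seq_len(nrow(bouts))) {
      hit <- FALSE
      for (b in buzz_times) {
        if (b >= bouts$start[i] && b <= bouts$end[i] &&
            ((b - sh) %% period) < on) hit <- TRUE
      }
      det <- det + hit
    }
    det / nrow(bouts)
  })
}
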