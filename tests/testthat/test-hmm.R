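toy_emis <- function(n, k, seed) {
  set.seed(seed)
  matrix(runif(n * k, 0.1, 1), n, k)
}

test_that("forward likelihood equals brute-force path summation", {
  trans <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE)
  init <- c(0.6, 0.4)
  for (n in c(1, 3, 7, 10)) {
    e <- toy_emis(n, 2, seed = n)
    expect_equal(batseg:::.hmm_forward_loglik(e, trans, init, 1L),
                 forward_oracle(e, trans, init), tolerance = 1e-10)
  }
  # three states too
  t3 <- matrix(c(0.8, 0.1, 0.1, 0.2, 0.6, 0.2, 0.1, 0.1, 0.8), 3, 3,
               byrow = TRUE)
  e3 <- toy_emis(6, 3, seed = 33)
  expect_equal(batseg:::.hmm_forward_loglik(e3, t3, rep(1/3, 3), 1L),
               forward_oracle(e3, t3, rep(1/3, 3)), tolerance = 1e-10)
  # independent sequences multiply (log-likelihoods add)
  e2 <- toy_emis(4, 2, seed = 4)
  expect_equal(
    batseg:::.hmm_forward_loglik(rbind(e2, e2), trans, init, c(1L, 5L)),
    2 * forward_oracle(e2, trans, init), tolerance = 1e-10)
})

test_that("initialization brackets the generative step-length means", {
  set.seed(31)
  x <- c(rnorm(500, 50, 10), rnorm(500, 80, 8))
  ini <- hmm_init(x, seed = 1)
  expect_lt(ini$step_mean[1], 60)
  expect_gt(ini$step_mean[2], 70)
  expect_true(ini$step_mean[1] < ini$step_mean[2])
  expect_equal(ini$kappa, c(0.1, 0.1))
  expect_warning(hmm_init(rnorm(500, 50, 5), seed = 1), "unimodal")
  expect_error(hmm_init(1:50), "100")
})

test_that("fitting recovers emission parameters from simulated data", {
  trans <- matrix(c(0.961, 0.039, 0.072, 0.928), 2, 2, byrow = TRUE)
  sim <- hmm_simulate(c(47, 84), c(27, 21), c(0.2, 11), trans, 3000,
                      seed = 32)
  m <- hmm_fit(sim$steps, seed = 1)
  expect_lt(max(abs(m$step_mean - c(47, 84)) / c(47, 84)), 0.1)
  expect_lt(max(abs(m$kappa - c(0.2, 11)) / c(0.2, 11)), 0.25)
  expect_gte(m$loglik, m$loglik_start)
  expect_true(all(abs(rowSums(m$trans) - 1) < 1e-12))
  # decoding beats 90% and states carry the slow = foraging convention
  dec <- hmm_decode(m, sim$steps)
  truth <- ifelse(sim$states == 1, "foraging", "commuting")
  expect_gt(mean(unclass(dec) == truth), 0.9)
  expect_equal(sum(unclass(dec) == "omitted"), 0)
})

test_that("pooled likelihood is invariant to trip order", {
  g1 <- generate_trip(seed = 33); g2 <- generate_trip(seed = 34)
  s1 <- compute_steps(regularize(g1$trip))
  s2 <- compute_steps(regularize(g2$trip))
  ini <- hmm_init(c(s1$step_length, s2$step_length), seed = 1)
  m12 <- hmm_fit(list(s1, s2), init = ini)
  m21 <- hmm_fit(list(s2, s1), init = ini)
  expect_equal(m12$loglik, m21$loglik, tolerance = 1e-6)
})

test_that("viterbi is constant under overwhelming emissions and optimal", {
  trans <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  e <- cbind(rep(1e-6, 20), rep(1, 20))   # state 2 everywhere
  v <- batseg:::.hmm_viterbi(e, trans, c(0.5, 0.5), 1L)
  expect_true(all(v == 2L))
  # viterbi path likelihood >= any constant-state path
  trans2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  e2 <- toy_emis(8, 2, seed = 8)
  v2 <- batseg:::.hmm_viterbi(e2, trans2, c(0.5, 0.5), 1L)
  path_ll <- function(s) {
    p <- log(0.5) + log(e2[1, s[1]])
    for (t in 2:8) p <- p + log(trans2[s[t - 1], s[t]]) + log(e2[t, s[t]])
    p
  }
  expect_gte(path_ll(v2), path_ll(rep(1L, 8)))
  expect_gte(path_ll(v2), path_ll(rep(2L, 8)))
})

test_that("posterior decoding mostly agrees with viterbi", {
  sim <- hmm_simulate(c(47, 84), c(27, 21), c(0.2, 11),
                      matrix(c(0.95, 0.05, 0.07, 0.93), 2, 2, byrow = TRUE),
                      500, seed = 35)
  m <- hmm_fit(sim$steps, seed = 1)
  v <- hmm_decode(m, sim$steps, method = "viterbi")
  p <- hmm_decode(m, sim$steps, method = "posterior")
  expect_gt(mean(unclass(v) == unclass(p)), 0.95)
})

test_that("Jarque-Bera matches the moment formula and flags heavy tails", {
  set.seed(36)
  x <- rnorm(1000)
  jb <- jarque_bera(x)
  m <- mean(x); s2 <- mean((x - m)^2)
  S <- mean((x - m)^3) / s2^1.5; K <- mean((x - m)^4) / s2^2
  expect_equal(jb$statistic, length(x) / 6 * (S^2 + (K - 3)^2 / 4))
  expect_equal(jb$df, 2)
  expect_gt(jb$p.value, 0.05)
  heavy <- rt(1000, df = 3)
  expect_lt(jarque_bera(heavy)$p.value, 0.01)
})

test_that("pseudo-residuals are near-normal under the true model", {
  sim <- hmm_simulate(c(47, 84), c(27, 21), c(0.2, 11),
                      matrix(c(0.95, 0.05, 0.07, 0.93), 2, 2, byrow = TRUE),
                      2000, seed = 37)
  m <- hmm_fit(sim$steps, seed = 1)
  pr <- hmm_pseudo_residuals(m, sim$steps)
  expect_lt(abs(mean(pr$step_resid, na.rm = TRUE)), 0.1)
  expect_lt(abs(sd(pr$step_resid, na.rm = TRUE) - 1), 0.1)
  expect_gt(pr$jb_step$p.value, 0.001)
  expect_true(is.finite(pr$jb_turn$statistic))
})

test_that("subsampling experiment: identity at base interval, OLS slope", {
  cfg <- sim_config(trip_hours_mean = 1.5, trip_hours_sd = 0.1,
                    p_omit = 0)
  gs <- lapply(41:43, function(s) generate_trip(cfg, seed = s))
  trips <- lapply(gs, `[[`, "trip")
  bts <- lapply(gs, function(g) g$truth$buzz_times_observed)
  res <- hmm_subsampling_experiment(trips, bts, intervals = c(15, 30, 60),
                                    seed = 1)
  expect_equal(nrow(res$table), 3)
  # OLS slope equals the closed-form least-squares estimate
  tab <- res$table
  slope_hand <- sum((tab$interval - mean(tab$interval)) *
                    (tab$median_ba - mean(tab$median_ba))) /
                sum((tab$interval - mean(tab$interval))^2)
  expect_equal(res$slope, slope_hand, tolerance = 1e-10)
  # base interval reproduces the plain pipeline
  steps <- lapply(trips, function(tr) compute_steps(regularize(tr)))
  m <- hmm_fit(steps, seed = 1)
  ba <- vapply(seq_along(trips), function(i) {
    bz <- assign_buzzes_to_fixes(data.frame(time = bts[[i]]), trips[[i]])
    score_trip(hmm_decode(m, steps[[i]]), buzz_fixes(bz))$balanced_accuracy
  }, numeric(1))
  expect_equal(res$table$median_ba[1], median(ba), tolerance = 1e-9)
})
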