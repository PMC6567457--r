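test_that("call detection places endpoints at the 5 dB drop", {
  # triangular pulse peaking 20 dB above the floor
  tt <- seq(0, 0.02, by = 1e-4)
  amp <- pmax(0, 20 - abs(tt - 0.01) / 5e-4 * 5)   # 5 dB per 0.5 ms
  calls <- detect_calls(data.frame(time = tt, amp_db = amp),
                        min_peak_db = 10)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$peak_amp, 20)
  # -5 dB crossings are 0.5 ms either side of the peak
  expect_lt(abs(calls$start - (0.01 - 5e-4)), 2e-4)
  expect_lt(abs(calls$end - (0.01 + 5e-4)), 2e-4)

  # silent envelope
  expect_equal(nrow(detect_calls(data.frame(time = tt, amp_db = 0 * tt))), 0)
})

test_that("synthetic search train is detected with ~6 ms durations", {
  env <- generate_call_train("search", n_calls = 6, envelope = TRUE)
  calls <- detect_calls(env$envelope)
  expect_equal(nrow(calls), 6)
  expect_true(all(abs(calls$end - calls$start - 0.006) < 0.0015))
})

test_that("two peaks closer than min_sep merge into the larger one", {
  tt <- seq(0, 0.01, by = 1e-5)
  amp <- rep(0, length(tt))
  amp[abs(tt - 0.004) < 4e-4] <- 18
  amp[abs(tt - 0.0045) < 3e-4] <- 20   # larger, 0.5 ms away
  calls <- detect_calls(data.frame(time = tt, amp_db = amp),
                        min_peak_db = 10, min_sep = 0.002)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$peak_amp, 20)
})

test_that("inter-pulse intervals are end-to-next-start", {
  calls <- data.frame(start = c(0, 0.210, 0.42), end = c(0.010, 0.216, 0.43))
  expect_equal(compute_ipis(calls), c(0.200, 0.204))
  expect_equal(compute_ipis(calls[1, ]), numeric())
  over <- data.frame(start = c(0, 0.005), end = c(0.010, 0.012))
  expect_error(compute_ipis(over), "negative")
})

test_that("buzz detection finds maximal sub-threshold runs of >= 3 calls", {
  mk <- function(ipis, dur = 0.003) {
    start <- cumsum(c(0, ipis + dur))
    data.frame(start = start, end = start + dur, peak_amp = 20)
  }
  b <- detect_buzzes(mk(c(0.005, 0.005)))
  expect_equal(nrow(b), 1); expect_equal(b$n_calls, 3)
  expect_false(b$aborted)

  expect_equal(nrow(detect_buzzes(mk(0.005))), 0)  # only 2 calls

  b2 <- detect_buzzes(mk(c(0.2, 0.008, 0.008, 0.008, 0.2, 0.005, 0.005)))
  expect_equal(nrow(b2), 2)
  expect_equal(b2$n_calls, c(4, 3))
  expect_true(b2$aborted[1])
  expect_false(b2$aborted[2])

  # invariant to pre/appended search-phase calls
  base <- mk(c(0.005, 0.006, 0.004))
  padded <- detect_buzzes(mk(c(0.2, 0.2, 0.005, 0.006, 0.004, 0.2, 0.2)))
  expect_equal(nrow(padded), 1)
  expect_equal(padded$n_calls, detect_buzzes(base)$n_calls)
})

test_that("buzzes map to the nearest fix, earlier on ties", {
  tr <- bat_trip(c(0, 15, 30), c(0, 1, 2), c(0, 0, 0))
  bz <- data.frame(time = c(7.4, 7.5, 20, 21, 22))
  out <- assign_buzzes_to_fixes(bz, tr)
  # 7.4 s is nearer the 0 s fix; 7.5 s is equidistant -> earlier fix
  expect_equal(out$fix_index, c(1L, 1L, 2L, 2L, 2L))
  expect_equal(buzz_fixes(out), c(1L, 2L))
  # 3 buzzes in one interval -> one buzz-positive fix
  expect_lte(length(buzz_fixes(out)), nrow(out))
  expect_warning(assign_buzzes_to_fixes(data.frame(time = 300), tr),
                 "dropped")
})

test_that("duty cycling keeps in-window buzzes and ~10% on average", {
  dc <- duty_cycle(0.5, 5)
  expect_equal(apply_duty_cycle(c(0.2, 2.7, 5.3), dc), c(0.2, 5.3))
  expect_equal(apply_duty_cycle(1:100, duty_cycle(5, 5)), 1:100)
  set.seed(3)
  bt <- runif(20000, 0, 3600)
  frac <- length(apply_duty_cycle(bt, dc)) / length(bt)
  expect_equal(frac, 0.1, tolerance = 0.01)
})

test_that("duty-cycle bout detection matches exhaustive enumeration", {
  dc <- duty_cycle()
  # dense buzzes: detected under every shift
  bouts <- data.frame(start = c(0, 300), end = c(60, 420))
  dense <- c(seq(0, 60, by = 0.4), seq(300, 420, by = 0.4))
  res <- duty_cycle_detection(dense, bouts, dc)
  expect_equal(res$per_shift$fraction, rep(1, 10))
  expect_equal(nrow(res$per_shift), 10)

  # sparse exponential gaps: equality with the brute-force oracle
  set.seed(7)
  bouts <- data.frame(start = seq(0, 1800, by = 300),
                      end = seq(0, 1800, by = 300) + 60)
  bt <- unlist(lapply(seq_len(nrow(bouts)), function(i) {
    g <- cumsum(rexp(60, 1 / 2))
    bouts$start[i] + g[g < 60]
  }))
  res <- duty_cycle_detection(bt, bouts, dc)
  expect_equal(res$per_shift$fraction, duty_oracle(bt, bouts))

  # single buzz per bout detects at on/period overall
  set.seed(8)
  b1 <- data.frame(start = seq(0, 49750, by = 250),
                   end = seq(0, 49750, by = 250) + 10)
  one <- b1$start + runif(nrow(b1), 0, 10)
  r1 <- duty_cycle_detection(one, b1, dc)
  expect_equal(r1$mean, 0.1, tolerance = 0.03)

  # non-decreasing in on-window
  r2 <- duty_cycle_detection(bt, bouts, duty_cycle(1, 5))
  expect_gte(r2$mean, res$mean)
  expect_error(duty_cycle_detection(bt, bouts[0, ], dc), "bout")
})

test_that("buzz bouts are maximal sub-60-s clusters", {
  bb <- buzz_bouts(c(0, 10, 20, 100, 110, 300))
  expect_equal(nrow(bb), 3)
  expect_equal(bb$n_buzzes, c(3L, 2L, 1L))
  expect_equal(nrow(buzz_bouts(numeric())), 0)
})
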