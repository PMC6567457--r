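test_that("track CSV round-trips and is sort-invariant", {
  tr <- straight_trip(20)
  f <- tempfile(fileext = ".csv")
  write_track(tr, f)
  back <- read_track(f)
  expect_equal(back$time, tr$time)
  expect_equal(back$x, tr$x, tolerance = 1e-9)
  expect_equal(trip_id(back), "straight")

  df <- utils::read.csv(f)
  df <- df[sample(nrow(df)), ]
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, f2, row.names = FALSE)
  expect_equal(as.data.frame(read_track(f2))[1:3],
               as.data.frame(back)[1:3])

  df$time[2] <- df$time[1]
  utils::write.csv(df, f2, row.names = FALSE)
  expect_error(read_track(f2), "duplicate")
})

test_that("lon/lat input is projected to planar meters consistent with geodesic distances", {
  skip_if_not_installed("geosphere")
  set.seed(1)
  lon <- -113.04 + cumsum(runif(30, 0, 0.003))
  lat <- 28.89 + cumsum(runif(30, 0, 0.003))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(`location-long` = lon, `location-lat` = lat,
                              timestamp = seq(0, by = 15, length.out = 30),
                              check.names = FALSE),
                   f, row.names = FALSE)
  tr <- read_track(f, utm_zone = 12)
  proj_d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  geo_d <- geosphere::distGeo(cbind(lon, lat))[1:29]
  # UTM scale distortion is < 0.1% within a zone
  expect_lt(max(abs(proj_d / geo_d - 1)), 1e-3)
})

test_that("filter_track drops points near the origin and rejects short tracks", {
  set.seed(2)
  n <- 150
  th <- seq(0, 4 * pi, length.out = n)
  r <- c(seq(10, 240, length.out = 30), seq(300, 3000, length.out = n - 30))
  tr <- bat_trip(seq(0, by = 15, length.out = n), r * cos(th), r * sin(th))
  out <- filter_track(tr, c(0, 0))
  expect_equal(nrow(out), 120)
  expect_true(all(sqrt(out$x^2 + out$y^2) > 250))
  # idempotent
  expect_equal(as.data.frame(filter_track(out, c(0, 0))),
               as.data.frame(out))
  # fewer than min_locations -> rejected
  expect_null(filter_track(tr, c(0, 0),
                           filter_config(min_locations = 121)))
  # all inside radius -> rejected
  expect_null(filter_track(tr, c(0, 0),
                           filter_config(exclusion_radius = 5000)))
  expect_error(filter_track(NULL, c(0, 0)), "empty")
})

test_that("step metrics: geometry, assignment convention, omitted count", {
  # collinear equally spaced: zero turns, constant speed
  st <- compute_steps(straight_trip(10, v = 5))
  expect_equal(st$turn_abs[2:9], rep(0, 8))
  expect_equal(st$speed[-1], rep(5, 9))
  expect_true(is.na(st$speed[1]))

  # right angle, 75 m legs at 15 s
  tr <- bat_trip(c(0, 15, 30), c(0, 75, 75), c(0, 0, 75))
  st <- compute_steps(tr)
  expect_equal(st$speed[2:3], c(5, 5))
  expect_equal(st$turn_abs[2], 90)
  expect_equal(st$turn_signed[2], pi / 2)

  # per trip exactly 2 locations lack the full (speed, turn) metric set
  for (seed in 1:3) {
    g <- generate_trip(sim_config(p_omit = 0), seed = seed)
    st <- compute_steps(g$trip)
    lacking <- sum(!(is.finite(st$speed) & is.finite(st$turn_abs)))
    expect_equal(lacking, 2)
  }
})

test_that("zero-length steps yield undefined turn angles", {
  tr <- bat_trip(c(0, 15, 30, 45), c(0, 10, 10, 20), c(0, 0, 0, 0))
  st <- compute_steps(tr)
  expect_true(is.na(st$turn_abs[2]))   # vertex into zero step
  expect_true(is.na(st$turn_abs[3]))   # vertex out of zero step
  expect_equal(st$speed[3], 0)
})

test_that("turn angles wrap to (-pi, pi]", {
  # sharp left turn just over pi/2 and a near-reversal
  tr <- bat_trip(c(0, 15, 30), c(0, 10, 9), c(0, 0, 0.5))
  st <- compute_steps(tr)
  expect_true(st$turn_signed[2] > pi / 2 && st$turn_signed[2] <= pi)
})

test_that("regularize restores the grid and interpolates linearly", {
  tr <- straight_trip(20)
  reg0 <- regularize(tr)
  expect_equal(reg0$time, tr$time)
  expect_equal(reg0$x, tr$x)
  expect_equal(reg0$y, tr$y)
  # one missing fix on a constant-speed run -> midpoint
  idx <- setdiff(1:20, 10)
  gap <- bat_trip(tr$time[idx], tr$x[idx], tr$y[idx])
  reg <- regularize(gap, dt = 15)
  expect_equal(nrow(reg), 20)
  expect_equal(reg$x[10], (tr$x[9] + tr$x[11]) / 2)
  expect_true(reg$interpolated[10])
  # interior has no undefined speeds after regularization
  st <- compute_steps(reg)
  expect_false(anyNA(st$speed[-1]))
})

test_that("regularize recovers deleted fixes within the GPS noise envelope", {
  g <- generate_trip(sim_config(p_omit = 0.1), seed = 5)
  reg <- regularize(g$trip, dt = 15)
  truth <- g$truth$clean
  miss <- reg$time[reg$interpolated]
  miss <- miss[miss %in% g$truth$omitted_times]
  expect_gt(length(miss), 0)
  # interpolated positions near the noiseless path: GPS noise (8 m, two
  # fixes averaged) plus within-state curvature at 15 s
  full <- generate_trip(sim_config(p_omit = 0), seed = 5)$truth$clean
  ix <- match(miss, full$time)
  iy <- match(miss, reg$time)
  err <- sqrt((reg$x[iy] - full$x[ix])^2 + (reg$y[iy] - full$y[ix])^2)
  expect_lt(stats::median(err), 40)
})

test_that("regularize splits trips at gaps longer than max_gap", {
  tt <- c(seq(0, 150, 15), seq(1000, 1150, 15))
  tr <- bat_trip(tt, seq_along(tt) * 10, rep(0, length(tt)))
  expect_warning(reg <- regularize(tr, dt = 15), "split")
  expect_equal(max(reg$block), 2)
  expect_false(any(reg$time > 150 & reg$time < 1000))
})

test_that("subsample keeps every k-th fix", {
  tr <- straight_trip(100)
  expect_equal(as.data.frame(subsample(tr, 15)), as.data.frame(tr))
  s30 <- subsample(tr, 30)
  expect_equal(nrow(s30), 50)
  expect_equal(attr(s30, "nominal_dt"), 30)
  expect_error(subsample(tr, 20), "multiple")
  # straight-line speed over longer intervals never exceeds the mean
  # step speed on a tortuous path (triangle inequality)
  g <- generate_trip(sim_config(p_omit = 0, gps_noise_sd = 0), seed = 2)
  sp1 <- compute_steps(g$trip)$speed
  sp4 <- compute_steps(subsample(g$trip, 60))$speed
  expect_lt(mean(sp4, na.rm = TRUE), mean(sp1, na.rm = TRUE) + 1e-9)
})
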