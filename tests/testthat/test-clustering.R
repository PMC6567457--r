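make_blobs <- function(centers, n_each = 100, sd = 0.5, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_each, centers[i, 1], sd),
          rnorm(n_each, centers[i, 2], sd))))
}

test_that("k-means recovers separated cluster centers", {
  pts <- make_blobs(rbind(c(3, 130), c(5, 20)), sd = 0.3)
  cm <- kmeans_fit(pts, 2, seed = 1)
  cen <- cm$centers[order(cm$centers[, 2]), ]
  # with full separation the centers are the empirical cloud means
  cloud2 <- colMeans(pts[101:200, ]); cloud1 <- colMeans(pts[1:100, ])
  expect_equal(as.numeric(cen[1, ]), as.numeric(cloud2), tolerance = 1e-9)
  expect_equal(as.numeric(cen[2, ]), as.numeric(cloud1), tolerance = 1e-9)
  expect_lt(max(abs(cen[2, ] - c(3, 130)) / c(3, 130)), 0.02)

  # k = 1 center is the grand mean
  cm1 <- kmeans_fit(pts, 1, seed = 1)
  expect_equal(as.numeric(cm1$centers), as.numeric(colMeans(pts)))

  # duplicating every point leaves the model unchanged
  cm2 <- kmeans_fit(rbind(pts, pts), 2, seed = 1)
  expect_equal(sort(cm2$centers[, 1]), sort(cm$centers[, 1]),
               tolerance = 1e-9)
  expect_error(kmeans_fit(pts[1, , drop = FALSE], 2), "distinct")
})

test_that("elbow criterion finds the generative number of clusters", {
  pts2 <- make_blobs(rbind(c(3, 130), c(5, 20)), sd = 0.4, seed = 2)
  expect_equal(elbow_select(pts2, 2:6, seed = 1)$k, 2)
  pts3 <- make_blobs(rbind(c(0, 0), c(40, 0), c(0, 40)), sd = 0.8,
                     seed = 3)
  expect_equal(elbow_select(pts3, 2:6, seed = 1)$k, 3)
  blob <- make_blobs(rbind(c(0, 0)), n_each = 300, seed = 4)
  expect_warning(res <- elbow_select(blob, 2:5, seed = 1), "elbow")
  expect_equal(res$k, 2)
})

test_that("kmC labels the slow/high-turn cluster as foraging", {
  accs <- vapply(11:13, function(s) {
    g <- generate_trip(seed = s)
    st <- compute_steps(g$trip)
    lab <- segment_kmc(st, seed = 1)
    ok <- unclass(lab) != "omitted"
    # omitted = the two path-end locations lacking a metric
    expect_equal(sum(unclass(lab) == "omitted"), 2)
    # foraging cluster has higher mean turn angle than commuting
    expect_gt(mean(st$turn_abs[unclass(lab) == "foraging"], na.rm = TRUE),
              mean(st$turn_abs[unclass(lab) == "commuting"], na.rm = TRUE))
    mean(unclass(lab)[ok] == g$truth$states[ok])
  }, numeric(1))
  expect_gt(mean(accs), 0.8)
})

test_that("kmC labels permute with location order", {
  g <- generate_trip(seed = 12)
  st <- compute_steps(g$trip)
  lab <- unclass(segment_kmc(st, seed = 3))
  set.seed(99); perm <- sample(nrow(st))
  lab_p <- unclass(segment_kmc(st[perm, ], seed = 3))
  expect_equal(lab_p, lab[perm])
})

test_that("15 synthetic trips leave 30 locations without kmC metrics", {
  bench <- make_benchmark_suite(sim_config(p_omit = 0), n_trips = 15,
                                seed = 2)
  omitted <- sum(vapply(bench$trips, function(g) {
    st <- compute_steps(g$trip)
    sum(!(is.finite(st$speed) & is.finite(st$turn_abs)))
  }, numeric(1)))
  expect_equal(omitted, 30)
})

test_that("four-region binary clustering recovers axis-aligned structure", {
  # four well-separated blobs at the LL/LH/HL/HH corners
  pts <- make_blobs(rbind(c(3, 20), c(3, 130), c(6, 20), c(6, 130)),
                    sd = 0.3, seed = 5)
  steps <- data.frame(speed = pts[, 1], turn_abs = pts[, 2])
  em <- embc_fit(steps, seed = 1)
  expect_true(em$speed_cut > 3 && em$speed_cut < 6)
  expect_true(em$turn_cut > 20 && em$turn_cut < 130)
  truth <- rep(c("LL", "LH", "HL", "HH"), each = 100)
  expect_equal(em$labels, truth)
  # labels are consistent with threshold comparison (axis-aligned)
  expect_equal(em$labels,
               paste0(ifelse(steps$speed > em$speed_cut, "H", "L"),
                      ifelse(steps$turn_abs > em$turn_cut, "H", "L")))
})

test_that("EMbC aggregation maps high-turn regions to foraging", {
  fake <- structure(list(labels = c("LL", "LH", "HL", "HH"),
                         speed_cut = 4, turn_cut = 75), class = "embc_labels")
  expect_equal(unclass(segment_embc(fake)),
               c("commuting", "foraging", "commuting", "foraging"))
  all_lh <- structure(list(labels = rep("LH", 5), speed_cut = 4,
                           turn_cut = 75), class = "embc_labels")
  expect_true(all(unclass(segment_embc(all_lh)) == "foraging"))
  # restricting the aggregation can only shrink the foraging set
  g <- generate_trip(seed = 13)
  em <- embc_fit(compute_steps(g$trip), seed = 1)
  both <- unclass(segment_embc(em)) == "foraging"
  lh_only <- unclass(segment_embc(em, foraging = "LH")) == "foraging"
  expect_true(all(lh_only <= both))
})

test_that("EMbC on generator defaults captures most true foraging in LH+HH", {
  rec <- vapply(14:16, function(s) {
    g <- generate_trip(seed = s)
    em <- embc_fit(compute_steps(g$trip), seed = 1)
    lab <- unclass(segment_embc(em))
    expect_equal(sum(lab == "omitted"), 0)   # every location labeled
    mean(lab[g$truth$states == "foraging"] == "foraging")
  }, numeric(1))
  expect_gt(mean(rec), 0.5)
})

test_that("degenerate features make the mixture fail loudly", {
  steps <- data.frame(speed = rep(3, 50), turn_abs = rep(10, 50))
  expect_error(embc_fit(steps), "converge|degenerate")
})
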