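#' K-means clustering of speed and turn angle
#'
#' Thin wrapper around [stats::kmeans()] (Lloyd-type minimization of
#' within-cluster squared error, best of `n_starts` restarts) on the
#' two-column feature matrix (speed m/s, absolute turn angle degrees).
#' Features are used unstandardized by default, which lets the
#' wide-ranged turn angle dominate the decision boundary -- in practice an
#' approximate turn-angle threshold.
#'
#' @param points matrix/data.frame with columns speed and turn_abs
#'   (finite rows only).
#' @param k number of clusters.
#' @param n_starts random restarts (default 10).
#' @param seed integer seed.
#' @param standardize z-score the features first (default `FALSE`).
#' @return list of class `cluster_model`: `k`, `centers`, `assignment`,
#'   `tot_withinss`, `variance_explained`.
#' @export
kmeans_fit <- function(points, k, n_starts = 10, seed = 1,
                       standardize = FALSE) {
  pts <- as.matrix(points)
  if (nrow(unique(pts)) < k) stop("need at least k distinct points")
  if (standardize) pts <- scale(pts)
  set.seed(seed)
  km <- stats::kmeans(pts, centers = k, nstart = n_starts, iter.max = 100)
  structure(list(k = k, centers = km$centers, assignment = km$cluster,
                 tot_withinss = km$tot.withinss,
                 variance_explained = km$betweenss / km$totss),
            class = "cluster_model")
}

#' Choose the number of clusters by the elbow criterion
#'
#' Computes variance explained over `k_range` and returns the k at the
#' sharpest bend: the largest second difference of the variance-explained
#' curve.  An elbow is only credited when the curve is essentially flat
#' beyond it (the next k adds less than `flat_tol` variance explained);
#' otherwise -- e.g. a single Gaussian blob, where variance explained
#' grows smoothly with every k -- there is no characteristic cluster
#' number and the smallest k is returned with a warning.
#'
#' @param points feature matrix as in [kmeans_fit()].
#' @param k_range ascending integer candidate k (default 2:10).
#' @param seed integer seed.
#' @param flat_tol largest variance-explained gain tolerated beyond the
#'   elbow (default 0.02).
#' @return list: `k`, `curve` (`data.frame` of k and variance explained).
#' @export
elbow_select <- function(points, k_range = 2:10, seed = 1,
                         flat_tol = 0.02) {
  stopifnot(!is.unsorted(k_range))
  ks <- c(max(1, min(k_range) - 1), k_range, max(k_range) + 1)
  ve <- vapply(ks, function(k)
    if (k == 1) 0 else kmeans_fit(points, k, seed = seed)$variance_explained,
    numeric(1))
  curve <- data.frame(k = ks, variance_explained = ve)
  gains <- diff(ve)                           # gain of moving to ks[i+1]
  d2 <- gains[-length(gains)] - gains[-1]     # second difference at interior k
  kk <- ks[2:(length(ks) - 1)]
  sel <- which.max(d2)
  if (max(gains) < flat_tol || gains[sel + 1] >= flat_tol) {
    warning("no clear elbow in the variance-explained curve; ",
            "returning smallest k")
    return(list(k = min(k_range), curve = curve[curve$k %in% k_range, ]))
  }
  list(k = kk[sel], curve = curve[curve$k %in% k_range, ])
}

#' Segment a trip by k-means clustering (kmC)
#'
#' Two-cluster k-means on (speed, absolute turn angle); the cluster with
#' the lower mean speed and higher mean turn angle is labeled foraging.
#' If the two criteria disagree, turn angle decides (foraging is the
#' high-turn cluster).  Locations lacking either metric (trip ends) are
#' omitted.
#'
#' @param steps a [compute_steps()] table.
#' @param seed integer seed.
#' @param n_starts restarts for k-means.
#' @return a [state_seq()].
#' @export
segment_kmc <- function(steps, seed = 1, n_starts = 10) {
  ok <- is.finite(steps$speed) & is.finite(steps$turn_abs)
  labels <- rep("omitted", nrow(steps))
  pts <- cbind(speed = steps$speed[ok], turn_abs = steps$turn_abs[ok])
  if (nrow(unique(pts)) < 2) {
    warning("degenerate step metrics; labeling everything commuting")
    labels[ok] <- "commuting"
    return(state_seq(labels))
  }
  cm <- kmeans_fit(pts, k = 2, n_starts = n_starts, seed = seed)
  forage_cl <- which.max(cm$centers[, "turn_abs"])   # turn angle decides
  labels[ok] <- ifelse(cm$assignment == forage_cl, "foraging", "commuting")
  state_seq(labels)
}

#' Four-region binary clustering of speed and turn angle
#'
#' Approximates expectation-maximization binary clustering: a
#' four-component bivariate Gaussian mixture (diagonal covariances, fit
#' with \pkg{mclust}) is reduced to axis-aligned low/high delimiters per
#' variable.  Binary clustering assigns each variable two low and two
#' high components, so the delimiter is the midpoint between the second
#' and third component means; every location is then labeled
#' LL/LH/HL/HH by threshold comparison (first letter: speed; second:
#' turn angle).  No location is omitted.
#'
#' @param steps a [compute_steps()] table.
#' @param seed integer seed.
#' @return list of class `embc_labels`: `labels` (per input row; `NA`
#'   metrics fall back to the nearest defined label), `speed_cut` (m/s),
#'   `turn_cut` (degrees).
#' @importFrom mclust Mclust mclustBIC
#' @export
embc_fit <- function(steps, seed = 1) {
  ok <- is.finite(steps$speed) & is.finite(steps$turn_abs)
  X <- cbind(speed = steps$speed[ok], turn = steps$turn_abs[ok])
  if (nrow(unique(X)) < 4 || any(apply(X, 2, stats::sd) < 1e-12))
    stop("mixture did not converge: degenerate (near-identical) features")
  set.seed(seed)
  fit <- mclust::Mclust(X, G = 4, modelNames = c("VVI", "VII", "EEI"),
                        verbose = FALSE)
  if (is.null(fit)) stop("mixture did not converge")
  mu <- t(fit$parameters$mean)                # 4 x 2 component means
  cut_of <- function(m) mean(sort(m)[2:3])    # two low, two high
  speed_cut <- cut_of(mu[, 1])
  turn_cut <- cut_of(mu[, 2])
  lab4 <- paste0(ifelse(X[, 1] > speed_cut, "H", "L"),
                 ifelse(X[, 2] > turn_cut, "H", "L"))
  labels <- rep(NA_character_, nrow(steps))
  labels[ok] <- lab4
  # undefined metrics at path ends inherit the nearest defined label
  if (anyNA(labels)) {
    idx <- which(!is.na(labels))
    near <- idx[pmax(1, findInterval(which(is.na(labels)), idx))]
    labels[is.na(labels)] <- labels[near]
  }
  structure(list(labels = labels, speed_cut = speed_cut,
                 turn_cut = turn_cut, mclust_bic = fit$bic),
            class = "embc_labels")
}

#' @export
print.embc_labels <- function(x, ...) {
  cat(sprintf("<embc_labels> delimiters: speed %.2f m/s, turn %.1f deg\n",
              x$speed_cut, x$turn_cut))
  print(table(x$labels))
  invisible(x)
}

#' Aggregate four-region labels into behavioral states
#'
#' By default the two high-turn regions (LH, HH) become foraging and the
#' low-turn regions (LL, HL) commuting; alternative aggregations can be
#' supplied.
#'
#' @param labels an [embc_fit()] result.
#' @param foraging regions mapped to foraging.
#' @return a [state_seq()].
#' @export
segment_embc <- function(labels, foraging = c("LH", "HH")) {
  state_seq(ifelse(labels$labels %in% foraging, "foraging", "commuting"))
}
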