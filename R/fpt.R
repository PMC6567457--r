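#' First-passage time through circles of given radii
#'
#' For each location, the first-passage time (FPT) is the time to first
#' exit a circle of radius `r` centered there, summed over the forward
#' and backward directions along the track.  Exit times are linearly
#' interpolated along the segment on which the distance from the center
#' first exceeds `r` (continuous-path convention), so a constant-speed
#' straight path has interior FPT exactly `2 r / v`.  Locations whose
#' circle is never exited in one of the two directions (path ends) get
#' `NA`.
#'
#' @param trip a [bat_trip()].
#' @param radii numeric vector of radii, m.
#' @return matrix `length(trip) x length(radii)` of seconds (`NA` where
#'   undefined); a single radius returns a vector.
#' @export
compute_fpt <- function(trip, radii) {
  stopifnot(all(radii > 0))
  n <- nrow(trip)
  tt <- trip$time; x <- trip$x; y <- trip$y
  one_dir <- function(i, forward) {
    idx <- if (forward) i:n else i:1
    d <- sqrt((x[idx] - x[i])^2 + (y[idx] - y[i])^2)
    dmax <- cummax(d)
    # first index (along idx) where the running max exceeds each radius
    pos <- findInterval(radii, dmax) + 1L      # dmax is nondecreasing
    out <- rep(NA_real_, length(radii))
    hit <- pos <= length(idx)
    if (any(hit)) {
      p <- pos[hit]
      j1 <- idx[p]; j0 <- idx[p - 1L]
      d1 <- d[p]; d0 <- d[p - 1L]
      frac <- (radii[hit] - d0) / (d1 - d0)
      frac[!is.finite(frac)] <- 1
      out[hit] <- abs(tt[j0] - tt[i]) + frac * abs(tt[j1] - tt[j0])
    }
    out
  }
  fpt <- matrix(NA_real_, n, length(radii))
  for (i in seq_len(n))
    fpt[i, ] <- one_dir(i, TRUE) + one_dir(i, FALSE)
  if (length(radii) == 1L) fpt[, 1] else fpt
}

#' Select the first-passage-time radius
#'
#' Computes the per-trip variance of log FPT at each candidate radius,
#' averages across trips, and returns the radius with the highest mean
#' variance -- the spatial scale at which the animals concentrate their
#' search.
#'
#' @param trips list of [bat_trip()]s.
#' @param radii candidate radii, m (default 100 to 5000 by 25).
#' @return list: `radius`, `var_curve` (`data.frame` of radius and mean
#'   variance of log FPT).
#' @export
select_radius <- function(trips, radii = seq(100, 5000, by = 25)) {
  if (length(radii) == 0) stop("empty radius grid")
  if (length(trips) == 0) stop("need at least one trip")
  vmat <- vapply(trips, function(tr) {
    fpt <- compute_fpt(tr, radii)
    if (length(radii) == 1L) fpt <- matrix(fpt, ncol = 1L)
    apply(fpt, 2, function(v) stats::var(log(v), na.rm = TRUE))
  }, numeric(length(radii)))
  vmat <- matrix(vmat, nrow = length(radii))
  mv <- rowMeans(vmat, na.rm = TRUE)
  curve <- data.frame(radius = radii, mean_var_log_fpt = mv)
  if (all(!is.finite(mv)) || diff(range(mv, finite = TRUE)) < 1e-10) {
    warning("flat variance curve (no characteristic scale); smallest radius")
    return(list(radius = radii[1], var_curve = curve))
  }
  list(radius = radii[which.max(mv)], var_curve = curve)
}

#' Foraging/commuting threshold from a log-FPT mixture
#'
#' Given a two-component normal mixture fitted to log FPT, the default
#' rule places the threshold at the 95th percentile of the lower-mean
#' component, clamped to lie between the two component means, and returns
#' it on the seconds scale.  The rule is pluggable via `rule`.
#'
#' @param mix a [fit_gauss_mixture()] result on `log(FPT)`.
#' @param level percentile of the lower component (default 0.95).
#' @param rule optional function(mix, level) returning a log-scale
#'   threshold, overriding the default.
#' @return threshold in seconds.
#' @export
fpt_threshold <- function(mix, level = 0.95, rule = NULL) {
  if (!is.null(rule)) return(exp(rule(mix, level)))
  if (!is_bimodal(mix))
    stop("mixture is not bimodal; supply a manual threshold")
  q <- stats::qnorm(level, mix$means[1], mix$sds[1])
  q <- min(max(q, mix$means[1]), mix$means[2])
  exp(q)
}

#' Segment a trip by first-passage time
#'
#' Locations with FPT above the threshold are foraging, at or below are
#' commuting, and locations without a defined FPT are omitted.
#'
#' @param fpt per-location FPT in seconds (vector; `NA` = undefined).
#' @param threshold seconds.
#' @return a [state_seq()].
#' @export
segment_fpt <- function(fpt, threshold) {
  stopifnot(threshold > 0)
  state_seq(ifelse(is.na(fpt), "omitted",
                   ifelse(fpt > threshold, "foraging", "commuting")))
}

#' Full first-passage-time segmentation pipeline
#'
#' Radius selection across trips, log-FPT mixture threshold, and
#' per-trip thresholding.
#'
#' @param trips list of [bat_trip()]s.
#' @param radii candidate radii (default 100-5000 m by 25).
#' @param radius fixed radius, bypassing selection.
#' @param threshold fixed threshold (s), bypassing the mixture rule.
#' @param level mixture percentile for [fpt_threshold()].
#' @param seed integer seed for the mixture restarts.
#' @return list: `radius`, `threshold`, `mix` (or `NULL`), `states`
#'   (list of [state_seq()] per trip), `fpt` (list of vectors).
#' @export
segment_fpt_pipeline <- function(trips, radii = seq(100, 5000, by = 25),
                                 radius = NULL, threshold = NULL,
                                 level = 0.95, seed = 1) {
  if (is.null(radius)) radius <- select_radius(trips, radii)$radius
  fpt <- lapply(trips, compute_fpt, radii = radius)
  mix <- NULL
  if (is.null(threshold)) {
    lf <- log(unlist(fpt))
    mix <- fit_gauss_mixture(lf[is.finite(lf)], seed = seed)
    threshold <- fpt_threshold(mix, level = level)
  }
  list(radius = radius, threshold = threshold, mix = mix,
       states = lapply(fpt, segment_fpt, threshold = threshold),
       fpt = fpt)
}
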