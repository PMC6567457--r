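#' Score a segmentation against buzz-positive fixes
#'
#' True positive rate (TPR) is the fraction of buzz-positive fixes
#' labeled foraging; true negative rate (TNR) the fraction of non-buzz
#' fixes labeled commuting; balanced accuracy their mean.  Omitted fixes
#' are excluded from both denominators.
#'
#' @param labels a [state_seq()] for one trip.
#' @param buzz_fixes integer indices of buzz-positive fixes (see
#'   [buzz_fixes()]).
#' @param trip_id optional identifier carried into the result.
#' @param method optional method name carried into the result.
#' @return one-row `data.frame`: `trip_id`, `method`, `tpr`, `tnr`,
#'   `balanced_accuracy`, `n_buzz_fixes`, `n_nonbuzz_fixes`, `omitted`.
#'   With no scorable buzz-positive fixes, `tpr` and `balanced_accuracy`
#'   are `NA` and the trip is flagged with a warning.
#' @export
score_trip <- function(labels, buzz_fixes, trip_id = "trip",
                       method = "method") {
  s <- unclass(state_seq(labels))
  n <- length(s)
  if (length(buzz_fixes) > 0 &&
      (min(buzz_fixes) < 1 || max(buzz_fixes) > n))
    stop("buzz fix indices outside the label sequence")
  is_buzz <- seq_len(n) %in% buzz_fixes
  use <- s != "omitted"
  pos <- use & is_buzz
  neg <- use & !is_buzz
  tpr <- if (sum(pos) == 0) NA_real_ else
    sum(s[pos] == "foraging") / sum(pos)
  tnr <- if (sum(neg) == 0) NA_real_ else
    sum(s[neg] == "commuting") / sum(neg)
  if (is.na(tpr)) warning("no scorable buzz-positive fixes; TPR undefined")
  data.frame(trip_id = trip_id, method = method, tpr = tpr, tnr = tnr,
             balanced_accuracy = (tpr + tnr) / 2,
             n_buzz_fixes = sum(pos), n_nonbuzz_fixes = sum(neg),
             omitted = sum(!use))
}

#' Summarize foraging segments of a labeling
#'
#' Segments are maximal runs of identical non-omitted labels (omitted
#' locations do not break runs).  Foraging percentage is over non-omitted
#' locations; durations are run length times the fix interval.
#'
#' @param labels a [state_seq()].
#' @param dt fix interval, s (default 15).
#' @return one-row `data.frame`: `percent_foraging`, `n_segments`
#'   (foraging segments), `mean_segment_duration_s`,
#'   `mean_segment_locations`.
#' @export
summarize_segments <- function(labels, dt = 15) {
  s <- unclass(state_seq(labels))
  segs <- state_segments(labels)
  fs <- segs[segs$state == "foraging", , drop = FALSE]
  nf <- sum(s == "foraging"); nu <- sum(s != "omitted")
  data.frame(
    percent_foraging = if (nu > 0) 100 * nf / nu else NA_real_,
    n_segments = nrow(fs),
    mean_segment_duration_s = if (nrow(fs)) mean(fs$n_locations) * dt
                              else NA_real_,
    mean_segment_locations = if (nrow(fs)) mean(fs$n_locations)
                             else NA_real_)
}

#' Friedman rank test across methods
#'
#' Tie-corrected Friedman chi-square over a complete trips x methods
#' score matrix (delegates to [stats::friedman.test()]).
#'
#' @param scores numeric matrix, rows = trips (blocks), columns =
#'   methods.
#' @return list: `chi2`, `df`, `p.value`.
#' @export
friedman_test <- function(scores) {
  m <- as.matrix(scores)
  if (anyNA(m)) stop("missing cells; Friedman test needs a complete matrix")
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 trips and >= 2 methods")
  ft <- stats::friedman.test(m)
  chi2 <- unname(ft$statistic); p <- ft$p.value
  if (!is.finite(chi2)) { chi2 <- 0; p <- 1 }  # every row fully tied
  list(chi2 = chi2, df = unname(ft$parameter), p.value = p)
}

#' Paired Wilcoxon signed-rank test with Bonferroni correction
#'
#' Zero differences are dropped before ranking (Wilcoxon's rule); the
#' null distribution is exact for 25 or fewer non-zero differences
#' without ties, and a tie-corrected normal approximation otherwise
#' (delegates to [stats::wilcox.test()]).
#'
#' @param x,y paired samples.
#' @param m number of comparisons in the family (Bonferroni multiplier).
#' @return list: `V` (signed-rank statistic), `p_raw`, `p_adj`, `n_used`
#'   (non-zero pairs).
#' @export
wilcoxon_paired <- function(x, y, m = 1) {
  stopifnot(length(x) == length(y), m >= 1)
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(V = 0, p_raw = 1, p_adj = 1, n_used = 0L))
  exact <- length(d) <= 25 && !anyDuplicated(abs(d))
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = !exact))
  list(V = unname(wt$statistic), p_raw = wt$p.value,
       p_adj = min(1, m * wt$p.value), n_used = length(d))
}

#' Compare per-method foraging parameters with buzz-location parameters
#'
#' For each method, pairs the per-trip mean foraging speed and turn angle
#' with the per-trip means at buzz-positive fixes and runs paired
#' Wilcoxon tests with Bonferroni correction over methods; reports means
#' and SDs across trips in the style of a state-parameter table.
#'
#' @param buzz_params `data.frame` with one row per trip: `speed`,
#'   `turn` (means at buzz fixes; `NA` rows, trips without buzzes, are
#'   excluded pairwise).
#' @param method_params named list of `data.frame`s (same shape) with
#'   per-trip foraging means for each method.
#' @return `data.frame`: one row per method plus a `buzz` reference row,
#'   with mean/SD of speed and turn and Bonferroni-adjusted p-values.
#' @export
compare_foraging_params <- function(buzz_params, method_params) {
  if (nrow(buzz_params) < 2) stop("need at least two trips")
  m <- length(method_params)
  rows <- lapply(names(method_params), function(nm) {
    mp <- method_params[[nm]]
    ok_s <- is.finite(buzz_params$speed) & is.finite(mp$speed)
    ok_t <- is.finite(buzz_params$turn) & is.finite(mp$turn)
    ws <- wilcoxon_paired(mp$speed[ok_s], buzz_params$speed[ok_s], m = m)
    wt <- wilcoxon_paired(mp$turn[ok_t], buzz_params$turn[ok_t], m = m)
    data.frame(method = nm,
               speed_mean = mean(mp$speed, na.rm = TRUE),
               speed_sd = stats::sd(mp$speed, na.rm = TRUE),
               speed_p_adj = ws$p_adj,
               turn_mean = mean(mp$turn, na.rm = TRUE),
               turn_sd = stats::sd(mp$turn, na.rm = TRUE),
               turn_p_adj = wt$p_adj)
  })
  ref <- data.frame(method = "buzz",
                    speed_mean = mean(buzz_params$speed, na.rm = TRUE),
                    speed_sd = stats::sd(buzz_params$speed, na.rm = TRUE),
                    speed_p_adj = NA_real_,
                    turn_mean = mean(buzz_params$turn, na.rm = TRUE),
                    turn_sd = stats::sd(buzz_params$turn, na.rm = TRUE),
                    turn_p_adj = NA_real_)
  rbind(do.call(rbind, rows), ref)
}
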