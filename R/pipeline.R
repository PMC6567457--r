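#' Segment a trip with one of the five methods
#'
#' Convenience dispatcher over the per-method pipelines.  `"kmc"` and
#' `"embc"` cluster (speed, absolute turn angle); `"fpt"` thresholds
#' first-passage time (radius/threshold taken from `...` or selected
#' automatically over `trips`); `"hmm"` fits and decodes the two-state
#' model; `"cvcp"` runs the change-point partition.
#'
#' @param trip a [bat_trip()].
#' @param method one of `"kmc"`, `"embc"`, `"fpt"`, `"hmm"`, `"cvcp"`.
#' @param seed integer seed.
#' @param ... method-specific arguments (e.g. `radius`, `threshold` for
#'   fpt; `model` for hmm to reuse a pooled fit).
#' @return a [state_seq()].
#' @export
segment_track <- function(trip, method = c("kmc", "embc", "fpt", "hmm",
                                           "cvcp"),
                          seed = 1, ...) {
  method <- match.arg(method)
  dots <- list(...)
  switch(method,
    kmc = segment_kmc(compute_steps(trip), seed = seed),
    embc = segment_embc(embc_fit(compute_steps(trip), seed = seed)),
    fpt = {
      res <- segment_fpt_pipeline(list(trip), radius = dots$radius,
                                  threshold = dots$threshold, seed = seed)
      res$states[[1]]
    },
    hmm = {
      steps <- compute_steps(regularize(trip))
      model <- dots$model
      if (is.null(model)) model <- hmm_fit(steps, seed = seed)
      hmm_decode(model, steps)
    },
    cvcp = segment_cvcp_pipeline(trip)$states)
}

#' Run the full five-method benchmark on synthetic trips
#'
#' Generates (or accepts) a benchmark suite, runs all five segmentation
#' methods with study-design settings -- pooled HMM fit across trips,
#' first-passage-time radius selected across trips and a common
#' log-FPT mixture threshold -- assigns the duty-cycle-observed buzzes
#' to fixes, and scores every trip under every method.
#'
#' @param bench a [make_benchmark_suite()] result.
#' @param seed integer seed for the method fits.
#' @param fpt_radii radius grid for the first-passage-time scale search.
#' @return list: `scores` (`data.frame`, one row per trip x method),
#'   `states` (nested list), `fpt` (radius/threshold used), `hmm` (the
#'   pooled model).
#' @export
run_benchmark <- function(bench, seed = 1,
                          fpt_radii = seq(100, 2000, by = 25)) {
  trips <- lapply(bench$trips, `[[`, "trip")
  truths <- lapply(bench$trips, `[[`, "truth")
  n <- length(trips)
  bz <- lapply(seq_len(n), function(i)
    buzz_fixes(assign_buzzes_to_fixes(
      data.frame(time = truths[[i]]$buzz_times_observed), trips[[i]])))
  steps <- lapply(trips, compute_steps)
  rsteps <- lapply(trips, function(tr) compute_steps(regularize(tr)))

  hmm <- hmm_fit(rsteps, seed = seed)
  fpt <- segment_fpt_pipeline(trips, radii = fpt_radii, seed = seed)

  states <- list(
    kmc = lapply(steps, segment_kmc, seed = seed),
    embc = lapply(steps, function(s) segment_embc(embc_fit(s, seed = seed))),
    fpt = fpt$states,
    hmm = lapply(rsteps, function(s) hmm_decode(hmm, s)),
    cvcp = lapply(trips, function(tr) segment_cvcp_pipeline(tr)$states))

  # hmm/fpt label counts can differ from the raw trip length only for
  # hmm (regularized grid); map decoded states back to observed fixes
  for (i in seq_len(n)) {
    rt <- regularize(trips[[i]])
    if (nrow(rt) != nrow(trips[[i]])) {
      keep <- !rt$interpolated
      states$hmm[[i]] <- state_seq(unclass(states$hmm[[i]])[keep])
    }
  }

  scores <- do.call(rbind, lapply(names(states), function(mth)
    do.call(rbind, lapply(seq_len(n), function(i)
      score_trip(states[[mth]][[i]], bz[[i]],
                 trip_id = trip_id(trips[[i]]), method = mth)))))
  list(scores = scores, states = states,
       fpt = list(radius = fpt$radius, threshold = fpt$threshold),
       hmm = hmm, buzz_fix_list = bz)
}
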