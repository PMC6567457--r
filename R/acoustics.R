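#' Detect echolocation calls in an amplitude envelope
#'
#' Scans a log-amplitude envelope for local maxima above a floor-relative
#' threshold, merging peaks closer than `min_sep` (keeping the larger), and
#' places call endpoints where the envelope first falls 5 dB below each
#' peak on either side.
#'
#' @param envelope `data.frame` with columns `time` (s) and `amp_db`.
#' @param min_peak_db minimum peak height above the envelope floor
#'   (median), in dB (default 10).
#' @param min_sep minimum separation between distinct peaks, s
#'   (default 0.002).
#' @param drop_db endpoint criterion: dB drop from the peak (default 5).
#' @return `data.frame` of calls: `start`, `end`, `peak_time`, `peak_amp`.
#' @export
detect_calls <- function(envelope, min_peak_db = 10, min_sep = 0.002,
                         drop_db = 5) {
  a <- envelope$amp_db; tt <- envelope$time
  n <- length(a)
  floor_db <- stats::median(a)
  thr <- floor_db + min_peak_db
  empty <- data.frame(start = numeric(), end = numeric(),
                      peak_time = numeric(), peak_amp = numeric())
  if (n < 3L) return(empty)
  is_peak <- which(a[2:(n - 1L)] > thr &
                   a[2:(n - 1L)] >= a[1:(n - 2L)] &
                   a[2:(n - 1L)] >= a[3:n]) + 1L
  if (length(is_peak) == 0L) return(empty)
  # merge peaks closer than min_sep, keeping the larger
  o <- is_peak[order(-a[is_peak])]
  kept <- integer()
  for (p in o)
    if (all(abs(tt[p] - tt[kept]) >= min_sep)) kept <- c(kept, p)
  kept <- sort(kept)
  calls <- lapply(kept, function(p) {
    cut <- a[p] - drop_db
    i0 <- p; while (i0 > 1L && a[i0 - 1L] > cut) i0 <- i0 - 1L
    i1 <- p; while (i1 < n && a[i1 + 1L] > cut) i1 <- i1 + 1L
    data.frame(start = tt[i0], end = tt[i1], peak_time = tt[p],
               peak_amp = a[p])
  })
  out <- do.call(rbind, calls)
  out <- out[order(out$start), , drop = FALSE]
  # plateau-topped pulses yield several coincident peaks whose 5 dB
  # regions overlap; merge overlapping calls, keeping the highest peak
  keep <- rep(TRUE, nrow(out))
  j <- 1L
  for (i in seq_len(nrow(out))[-1]) {
    if (out$start[i] <= out$end[j]) {
      out$end[j] <- max(out$end[j], out$end[i])
      if (out$peak_amp[i] > out$peak_amp[j]) {
        out$peak_amp[j] <- out$peak_amp[i]
        out$peak_time[j] <- out$peak_time[i]
      }
      keep[i] <- FALSE
    } else j <- i
  }
  out[keep, , drop = FALSE]
}

#' Inter-pulse intervals of a call sequence
#'
#' IPI is the time between the end of one call and the start of the next.
#'
#' @param calls `data.frame` with `start` and `end`, sorted by `start`.
#' @return numeric vector of length `nrow(calls) - 1`.
#' @export
compute_ipis <- function(calls) {
  if (nrow(calls) < 2L) return(numeric())
  if (is.unsorted(calls$start)) stop("calls must be sorted by start time")
  ipi <- calls$start[-1L] - calls$end[-nrow(calls)]
  if (any(ipi < 0)) stop("overlapping calls produce negative IPIs")
  ipi
}

#' Detect feeding buzzes in a call sequence
#'
#' A buzz is a maximal run of at least `min_calls` consecutive calls whose
#' inter-pulse intervals are all below `ipi_threshold`.  Both terminal and
#' aborted buzzes qualify: a run followed by further search-phase calls is
#' flagged `aborted` but still counts as a prey-capture attempt.
#'
#' @param calls sorted call `data.frame` (`start`, `end`).
#' @param ipi_threshold s (default 0.010).
#' @param min_calls minimum calls per buzz (default 3).
#' @return `data.frame` of buzzes: `time` (start of first call), `n_calls`,
#'   `aborted`.
#' @export
detect_buzzes <- function(calls, ipi_threshold = 0.010, min_calls = 3) {
  empty <- data.frame(time = numeric(), n_calls = integer(),
                      aborted = logical())
  if (nrow(calls) < min_calls) return(empty)
  ipi <- compute_ipis(calls)
  fast <- ipi < ipi_threshold
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  runs <- which(r$values & r$lengths >= min_calls - 1L)
  if (length(runs) == 0L) return(empty)
  do.call(rbind, lapply(runs, function(j) {
    i0 <- starts[j]              # first call of the run
    i1 <- ends[j] + 1L           # last call of the run
    data.frame(time = calls$start[i0], n_calls = i1 - i0 + 1L,
               aborted = i1 < nrow(calls))
  }))
}

#' Assign buzzes to the nearest GPS fix
#'
#' Each buzz is mapped to the trip location whose time is closest;
#' equidistant buzzes go to the earlier fix.  Buzzes more than
#' `max_outside` seconds outside the trip's time span are dropped with a
#' warning.
#'
#' @param buzzes `data.frame` with a `time` column (s, on the trip clock).
#' @param trip a [bat_trip()].
#' @param max_outside tolerance outside the span (default 5 s, the audio
#'   schedule period).
#' @return `buzzes` with a `fix_index` column added (rows outside the span
#'   removed).
#' @export
assign_buzzes_to_fixes <- function(buzzes, trip, max_outside = 5) {
  if (nrow(buzzes) == 0L) { buzzes$fix_index <- integer(); return(buzzes) }
  inside <- buzzes$time >= trip$time[1] - max_outside &
            buzzes$time <= trip$time[nrow(trip)] + max_outside
  if (any(!inside))
    warning(sum(!inside), " buzz(es) outside trip time span dropped")
  buzzes <- buzzes[inside, , drop = FALSE]
  buzzes$fix_index <- vapply(buzzes$time, function(tb) {
    d <- abs(tb - trip$time)
    which(d == min(d))[1L]       # tie -> earlier fix
  }, integer(1))
  buzzes
}

#' Indices of buzz-positive fixes
#'
#' @param buzzes output of [assign_buzzes_to_fixes()].
#' @return sorted unique fix indices with at least one buzz.
#' @export
buzz_fixes <- function(buzzes) sort(unique(buzzes$fix_index))

#' Audio duty cycle
#'
#' @param on_window seconds of audio recorded per period (default 0.5).
#' @param period schedule period in seconds (default 5).
#' @export
duty_cycle <- function(on_window = 0.5, period = 5) {
  stopifnot(on_window > 0, on_window <= period)
  list(on_window = on_window, period = period)
}

#' Keep only buzzes falling inside duty-cycled recording windows
#'
#' @param buzz_times numeric buzz times (s).
#' @param dc a [duty_cycle()].
#' @param shift window phase offset in `[0, period)`.
#' @export
apply_duty_cycle <- function(buzz_times, dc = duty_cycle(), shift = 0) {
  stopifnot(shift >= 0, shift < dc$period)
  ph <- (buzz_times - shift) %% dc$period
  buzz_times[ph < dc$on_window]
}

#' Foraging-bout detection rate under a duty-cycled recorder
#'
#' For every possible phase shift of the recording schedule (multiples of
#' the on-window, `period / on_window` shifts in all), counts the fraction
#' of ground-truth foraging bouts containing at least one buzz inside an
#' on-window.
#'
#' @param buzz_times numeric buzz times (s), continuous-audio ground truth.
#' @param bouts `data.frame` with `start` and `end` of each bout (s).
#' @param dc a [duty_cycle()].
#' @return list with `per_shift` (`data.frame` of `shift`, `fraction`),
#'   `mean`, and `sd`.
#' @export
duty_cycle_detection <- function(buzz_times, bouts, dc = duty_cycle()) {
  if (nrow(bouts) == 0L) stop("no bouts supplied")
  shifts <- seq(0, dc$period - dc$on_window, by = dc$on_window)
  frac <- vapply(shifts, function(s) {
    obs <- apply_duty_cycle(buzz_times, dc, shift = s)
    hit <- vapply(seq_len(nrow(bouts)), function(i)
      any(obs >= bouts$start[i] & obs <= bouts$end[i]), logical(1))
    mean(hit)
  }, numeric(1))
  list(per_shift = data.frame(shift = shifts, fraction = frac),
       mean = mean(frac), sd = stats::sd(frac))
}

#' Group buzz times into bouts
#'
#' A bout is a maximal set of buzzes separated by gaps shorter than
#' `max_gap` (default 60 s).
#'
#' @param buzz_times sorted numeric buzz times (s).
#' @param max_gap seconds (default 60).
#' @return `data.frame` with `start`, `end`, `n_buzzes` per bout.
#' @export
buzz_bouts <- function(buzz_times, max_gap = 60) {
  if (length(buzz_times) == 0L)
    return(data.frame(start = numeric(), end = numeric(),
                      n_buzzes = integer()))
  bt <- sort(buzz_times)
  grp <- cumsum(c(1, as.integer(diff(bt) >= max_gap)))
  do.call(rbind, lapply(split(bt, grp), function(v)
    data.frame(start = v[1], end = v[length(v)], n_buzzes = length(v))))
}
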