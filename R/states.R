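#' Behavioral-state sequences
#'
#' States are per-location character labels: `"foraging"`, `"commuting"`,
#' or `"omitted"` (locations a method could not classify, e.g. path ends
#' lacking a turn angle or a first-passage time).
#'
#' @param labels character vector of labels.
#' @return validated character vector of class `state_seq`.
#' @export
state_seq <- function(labels) {
  labels <- as.character(labels)
  ok <- labels %in% c("foraging", "commuting", "omitted")
  if (!all(ok)) stop("unknown state label(s): ",
                     paste(unique(labels[!ok]), collapse = ", "))
  structure(labels, class = "state_seq")
}

#' @export
print.state_seq <- function(x, ...) {
  tb <- table(factor(unclass(x),
                     levels = c("foraging", "commuting", "omitted")))
  cat(sprintf("<state_seq> %d locations: %d foraging, %d commuting, %d omitted\n",
              length(x), tb[["foraging"]], tb[["commuting"]], tb[["omitted"]]))
  invisible(x)
}

#' Run-length segments of a state sequence
#'
#' Maximal runs of identical non-omitted labels.  Omitted locations do not
#' break a run: a run interrupted only by omitted locations continues
#' (omitted fixes carry no behavioral information).
#'
#' @param states a [state_seq()] or character vector.
#' @return `data.frame` with `state`, `start`, `end` (location indices) and
#'   `n_locations` per segment.
#' @export
state_segments <- function(states) {
  s <- unclass(state_seq(states))
  keep <- which(s != "omitted")
  if (length(keep) == 0L)
    return(data.frame(state = character(), start = integer(),
                      end = integer(), n_locations = integer()))
  r <- rle(s[keep])
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(state = r$values,
             start = keep[starts], end = keep[ends],
             n_locations = r$lengths)
}

#' Read / write per-location label tables
#'
#' The label CSV dialect is `trip_id, time_s, state`.
#'
#' @param trip a [bat_trip()] providing times.
#' @param states a [state_seq()].
#' @param path CSV path.
#' @export
write_labels <- function(trip, states, path) {
  utils::write.csv(data.frame(trip_id = trip_id(trip), time_s = trip$time,
                              state = unclass(states)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path)
  df$state <- state_seq(df$state)
  df
}
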