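#' Build per-animal antenna occupancy intervals from the event stream
#'
#' The tracking platform logs only detection *changes*: an `IN` row when an
#' animal's chip appears in an antenna field and an `OUT` row when it
#' disappears. This function pairs them into half-open occupancy intervals
#' `[start, end)` per `(animal, antenna)`. Because an animal is often picked
#' up by the next antenna before the previous one logs its exit (the
#' "doubling" phenomenon), intervals of one animal on *different* antennas
#' may overlap briefly; that overlap is retained, not treated as an error.
#' An `IN` with no matching `OUT` by the end of the stream leaves an open
#' interval (`end = NA`): the animal is still detected there, or it left the
#' detection range (e.g. climbed into the running wheel).
#'
#' Anomalies: an `OUT` with no matching open interval, or a repeated `IN` on
#' an already-open `(animal, antenna)`, is skipped with a warning (an error
#' when `strict = TRUE`).
#'
#' @param events Event tibble from [read_sca()] or [simulate_cage()],
#'   ordered by timestamp (ties broken by row order).
#' @param strict If `TRUE`, anomalous rows abort instead of being skipped.
#' @return A tibble with columns `animal_id`, `antenna`, `start`, `end`
#'   (POSIXct; `NA` end = open), ordered by `animal_id` then `start`.
#' @seealso [detection_state()], [field_changes()]
#' @export
build_occupancy <- function(events, strict = FALSE) {
  stopifnot(all(c("timestamp", "animal_id", "antenna", "direction") %in% names(events)))
  n <- nrow(events)
  if (n == 0) {
    return(tibble::tibble(animal_id = character(0), antenna = integer(0),
                          start = ms_to_posix(numeric(0)), end = ms_to_posix(numeric(0))))
  }
  if (is.unsorted(events$timestamp)) {
    stop("events must be ordered by timestamp", call. = FALSE)
  }
  ts <- posix_to_ms(events$timestamp)
  key <- paste(events$animal_id, events$antenna, sep = "\r")
  is_in <- events$direction == "IN"

  open_start <- new.env(parent = emptyenv())   # key -> ms of open IN
  res_animal <- character(n); res_ant <- integer(n)
  res_start <- numeric(n); res_end <- numeric(n)
  k <- 0L
  anomalies <- integer(0)
  for (i in seq_len(n)) {
    ki <- key[[i]]
    open <- get0(ki, envir = open_start)
    if (is_in[[i]]) {
      if (is.null(open)) {
        assign(ki, ts[[i]], envir = open_start)
      } else {
        anomalies <- c(anomalies, i)  # repeated IN, ignored
      }
    } else {
      if (is.null(open)) {
        anomalies <- c(anomalies, i)  # unmatched OUT, ignored
      } else {
        k <- k + 1L
        res_animal[[k]] <- events$animal_id[[i]]
        res_ant[[k]] <- events$antenna[[i]]
        res_start[[k]] <- open
        res_end[[k]] <- ts[[i]]
        rm(list = ki, envir = open_start)
      }
    }
  }
  if (length(anomalies)) {
    msg <- paste0(length(anomalies), " anomalous event row(s) (repeated IN or unmatched OUT) at row(s) ",
                  paste(utils::head(anomalies, 5), collapse = ", "),
                  if (length(anomalies) > 5) " ..." else "")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  # open intervals left at end of stream
  left <- ls(open_start)
  if (length(left)) {
    parts <- strsplit(left, "\r", fixed = TRUE)
    for (j in seq_along(left)) {
      k <- k + 1L
      res_animal[[k]] <- parts[[j]][1]
      res_ant[[k]] <- as.integer(parts[[j]][2])
      res_start[[k]] <- get(left[[j]], envir = open_start)
      res_end[[k]] <- NA_real_
    }
  }
  out <- tibble::tibble(
    animal_id = res_animal[seq_len(k)],
    antenna = res_ant[seq_len(k)],
    start = ms_to_posix(res_start[seq_len(k)]),
    end = ms_to_posix(res_end[seq_len(k)])
  )
  out[order(out$animal_id, out$start, out$end), , drop = FALSE]
}

#' Count deduplicated antenna field changes in a time window
#'
#' The field-change count is the surrogate for spontaneous cage activity.
#' Summing raw table rows overcounts: each crossing logs both an `IN` on the
#' new antenna and an `OUT` from the previous one, and the `OUT` frequently
#' arrives *after* the next `IN` (doubling). The dedup rule therefore uses
#' only `IN` rows: restrict to the animal's `IN` events inside the half-open
#' window `[window[1], window[2])` and count consecutive pairs whose antenna
#' labels differ. `OUT` rows and repeated `IN`s on the same antenna
#' contribute nothing, so the count is invariant to how many exit rows the
#' logger emitted.
#'
#' @param events Event tibble ordered by timestamp.
#' @param animal_id Animal to count; an unknown id yields 0 with a warning.
#' @param window Length-2 POSIXct (or coercible) vector, half-open
#'   `[from, to)`.
#' @param carry_state If `TRUE`, the animal's last known antenna before the
#'   window start is prepended, so a crossing that straddles the boundary is
#'   counted; by default windows are independent.
#' @return A non-negative integer count.
#' @export
field_changes <- function(events, animal_id, window, carry_state = FALSE) {
  stopifnot(length(window) == 2)
  w <- posix_to_ms(as.POSIXct(window, tz = scave_tz))
  if (w[2] < w[1]) stop("window must satisfy from <= to", call. = FALSE)
  if (!animal_id %in% events$animal_id) {
    warning("animal ", animal_id, " has no events", call. = FALSE)
    return(0L)
  }
  ev <- events[events$animal_id == animal_id & events$direction == "IN", , drop = FALSE]
  ts <- posix_to_ms(ev$timestamp)
  ant <- ev$antenna[ts >= w[1] & ts < w[2]]
  if (carry_state) {
    prev <- ev$antenna[ts < w[1]]
    if (length(prev)) ant <- c(prev[length(prev)], ant)
  }
  if (length(ant) < 2) return(0L)
  sum(diff(ant) != 0L)
}

#' Detection state of one animal at a time point
#'
#' An animal is *detected* at time `at` iff at least one of its occupancy
#' intervals is open at `at` (half-open convention: an interval `[s, e)`
#' covers `at` when `s <= at < e`; an interval with `NA` end covers all
#' `at >= s`). An animal whose last logged event was an `IN` is therefore
#' continuously detected while it rests; an animal that produced an `OUT`
#' and nothing since (typically: it climbed into the running wheel, whose
#' distance and material block the chip) is undetected.
#'
#' @param intervals Occupancy tibble from [build_occupancy()].
#' @param animal_id Animal to query.
#' @param at POSIXct time point.
#' @return A list with `animal_id`, `at`, `detected` (logical) and
#'   `last_closed_antenna` (integer or `NA`): the antenna of the most
#'   recently closed interval with `end <= at`, ties broken by later start.
#' @export
detection_state <- function(intervals, animal_id, at) {
  at_ms <- posix_to_ms(as.POSIXct(at, tz = scave_tz))
  iv <- intervals[intervals$animal_id == animal_id, , drop = FALSE]
  s <- posix_to_ms(iv$start); e <- posix_to_ms(iv$end)
  detected <- any(s <= at_ms & (is.na(e) | e > at_ms))
  closed <- !is.na(e) & e <= at_ms
  last_ant <- NA_integer_
  if (any(closed)) {
    j <- which(closed)
    j <- j[order(e[j], s[j])]
    last_ant <- iv$antenna[[j[length(j)]]]
  }
  list(animal_id = animal_id, at = ms_to_posix(at_ms),
       detected = detected, last_closed_antenna = last_ant)
}
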