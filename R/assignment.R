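#' Wheel placement and strictness configuration
#'
#' The attribution method requires the running wheel to stand on known
#' antenna fields (antennas 1 and 2 in the reference setup). A wheel-active
#' minute is credited to an animal that (a) last entered a wheel antenna and
#' (b) was not detected by any antenna while the wheel rotated — an animal
#' inside the wheel is invisible to the platform because of distance and the
#' wheel's material.
#'
#' @param wheel_antennas Integer antenna labels the wheel stands on;
#'   non-empty subset of 1..6. Default `c(1, 2)`.
#' @param strictness Either `"whole-minute"` (premise (b) requires zero
#'   detection anywhere in the rotation minute; default) or a numeric
#'   overlap fraction `f` in `[0, 1)`: the animal may be detected for at
#'   most `f` of the minute, which tolerates mid-minute wheel entry/exit.
#' @param max_gap_s Optional upper bound, in seconds, on the gap between the
#'   animal's exit from the wheel antenna and the start of the rotation
#'   minute. Default `Inf`: premise (a) only constrains *which* antenna was
#'   last entered, not when.
#' @return A list of class `wheel_config`.
#' @export
wheel_config <- function(wheel_antennas = c(1L, 2L), strictness = "whole-minute",
                         max_gap_s = Inf) {
  wheel_antennas <- as.integer(wheel_antennas)
  if (length(wheel_antennas) == 0 || !all(wheel_antennas %in% 1:6)) {
    stop("wheel_antennas must be a non-empty subset of 1..6", call. = FALSE)
  }
  if (identical(strictness, "whole-minute")) {
    max_detect_frac <- 0
  } else if (is.numeric(strictness) && length(strictness) == 1 &&
             strictness >= 0 && strictness < 1) {
    max_detect_frac <- as.numeric(strictness)
  } else {
    stop("strictness must be \"whole-minute\" or a fraction in [0, 1)", call. = FALSE)
  }
  structure(list(wheel_antennas = wheel_antennas, strictness = strictness,
                 max_detect_frac = max_detect_frac,
                 max_gap_s = as.numeric(max_gap_s)),
            class = "wheel_config")
}

#' @export
print.wheel_config <- function(x, ...) {
  cat("wheel_config: antennas {", paste(x$wheel_antennas, collapse = ","),
      "}, strictness ", if (x$max_detect_frac == 0) "whole-minute" else
        paste0("detected <= ", x$max_detect_frac, " of minute"),
      ", max gap ", x$max_gap_s, " s\n", sep = "")
  invisible(x)
}

# Per-animal index structures for fast minute queries
animal_index <- function(intervals, animal_id) {
  iv <- intervals[intervals$animal_id == animal_id, , drop = FALSE]
  s <- posix_to_ms(iv$start)
  e <- posix_to_ms(iv$end)
  e_eff <- ifelse(is.na(e), Inf, e)
  o <- order(s, e_eff)
  s <- s[o]; e_eff <- e_eff[o]; ant <- iv$antenna[o]
  # merged union of detection intervals (already sorted by start)
  if (length(s)) {
    run_end <- cummax(e_eff)
    new_run <- c(TRUE, s[-1] > run_end[-length(run_end)])
    grp <- cumsum(new_run)
    m_s <- tapply(s, grp, min)
    m_e <- tapply(e_eff, grp, max)
    m_len <- m_e - m_s
    cum <- cumsum(ifelse(is.finite(m_len), m_len, 0))
  } else {
    m_s <- m_e <- m_len <- cum <- numeric(0)
  }
  list(starts = s, ends = e_eff, antenna = ant,
       m_s = as.numeric(m_s), m_e = as.numeric(m_e), cum = as.numeric(cum))
}

# total detected ms in (-Inf, t] against the merged intervals
covered_upto <- function(ix, t) {
  i <- findInterval(t, ix$m_s)
  i1 <- pmax(i, 1)
  cum0 <- c(0, ix$cum)  # cum0[k] = total length of merged intervals 1..k-1
  part <- pmin(pmax(t - ix$m_s[i1], 0), ix$m_e[i1] - ix$m_s[i1])
  out <- cum0[i1] + part
  out[i == 0] <- 0
  out
}

# for a vector of rotation intervals [a, b) (ms), return per-minute logical
# premise vectors for one animal
animal_premises <- function(ix, a, b, config) {
  n <- length(a)
  if (length(ix$starts) == 0) {
    return(list(positional = rep(FALSE, n), undetected = rep(TRUE, n)))
  }
  # (a): latest interval started inside the half-open rotation window or
  # earlier (start < b) is on a wheel antenna
  j <- findInterval(b - 1, ix$starts)
  positional <- j > 0 & ix$antenna[pmax(j, 1)] %in% config$wheel_antennas
  if (is.finite(config$max_gap_s)) {
    ends_j <- ix$ends[pmax(j, 1)]
    # a closed qualifying interval must have ended within max_gap_s of the
    # rotation start; an open interval has not ended and passes the gap test
    positional <- positional &
      (!is.finite(ends_j) | ends_j >= a - config$max_gap_s * 1000)
  }
  # (b): detected time within [a, b) at most f of the interval
  det_ms <- covered_upto(ix, b) - covered_upto(ix, a)
  undetected <- det_ms <= config$max_detect_frac * (b - a) + 1e-6
  list(positional = positional, undetected = undetected)
}

#' Animals qualifying for credit of one wheel-active minute
#'
#' Applies the two premises to every animal over the rotation interval
#' `[minute_start, minute_start + 60 s)`: (a) the animal's most recent
#' antenna entry (at or before the end of the interval) was on a wheel
#' antenna, and (b) the animal was not detected by any antenna during the
#' interval (or, under fractional strictness, for at most that fraction of
#' it). The empty set is a legal outcome and leads to a discard.
#'
#' @param intervals Occupancy tibble from [build_occupancy()].
#' @param minute_start POSIXct start of the wheel-active minute.
#' @param config A [wheel_config()].
#' @param animals Character vector of animal ids to consider; defaults to
#'   all animals present in `intervals`.
#' @return Character vector of qualifying animal ids (possibly empty).
#' @export
candidates <- function(intervals, minute_start, config = wheel_config(),
                       animals = NULL) {
  if (is.null(animals)) animals <- sort(unique(intervals$animal_id))
  a <- posix_to_ms(as.POSIXct(minute_start, tz = scave_tz))
  b <- a + 60000
  ok <- vapply(animals, function(id) {
    p <- animal_premises(animal_index(intervals, id), a, b, config)
    p$positional && p$undetected
  }, logical(1))
  animals[ok]
}

#' Credit wheel-active minutes to individual animals
#'
#' The core attribution step: for every per-minute wheel record with at
#' least one rotation, determine which animal(s) were exercising. A minute
#' is `ASSIGNED` when exactly one animal satisfies both premises (see
#' [wheel_config()]), `ASSIGNED_MULTI` when several do (two animals can
#' share the wheel; the full rotation count is credited to each, not
#' split), and `DISCARDED` when none does — e.g. an animal nudging the wheel
#' from outside while detected on a wheel antenna, or a human moving the
#' cage. Minutes with zero rotations produce no result row.
#'
#' @param events SCA event tibble (all animals of the cage).
#' @param ve VE minute tibble from [read_ve()] or [simulate_cage()].
#' @param config A [wheel_config()].
#' @param roster Optional explicit character vector of animal ids. Defaults
#'   to every RFID seen in `events`; pinning the roster makes a failed chip
#'   visible instead of silently shrinking the cage.
#' @param coverage Optional POSIXct length-2 vector giving the time range
#'   over which the tracking platform was recording. Wheel-active minutes
#'   outside it are discarded with reason `NO_CANDIDATE` and a warning.
#'   Defaults to the event timestamp range.
#' @return A tibble with one row per wheel-active minute: `minute_start`,
#'   `rot_total`, `active_seconds`, `credited` (list of animal ids),
#'   `n_credited`, `status` (`ASSIGNED` / `ASSIGNED_MULTI` / `DISCARDED`)
#'   and `reason` (`NONE` / `NO_CANDIDATE` / `ALL_CANDIDATES_DETECTED`).
#' @seealso [discard_report()], [hourly_table()]
#' @export
assign_ve <- function(events, ve, config = wheel_config(), roster = NULL,
                      coverage = NULL) {
  stopifnot(inherits(config, "wheel_config"))
  if (is.null(roster)) roster <- sort(unique(events$animal_id))
  if (length(roster) == 0) stop("no animals in SCA stream and no roster given", call. = FALSE)
  active <- ve[ve$rot_total > 0, , drop = FALSE]
  if (nrow(active) == 0) return(empty_assignments())

  intervals <- build_occupancy(events)
  a <- posix_to_ms(active$minute_start)
  b <- a + 60000
  if (is.null(coverage)) coverage <- range(events$timestamp)
  cov <- posix_to_ms(as.POSIXct(coverage, tz = scave_tz))
  covered <- a >= cov[1] & b <= cov[2]
  if (any(!covered)) {
    warning(sum(!covered), " wheel-active minute(s) outside SCA coverage discarded",
            call. = FALSE)
  }

  pos <- matrix(FALSE, nrow(active), length(roster))
  und <- matrix(FALSE, nrow(active), length(roster))
  for (j in seq_along(roster)) {
    p <- animal_premises(animal_index(intervals, roster[[j]]), a, b, config)
    pos[, j] <- p$positional
    und[, j] <- p$undetected
  }
  qual <- pos & und & covered
  credited <- lapply(seq_len(nrow(active)), function(i) roster[qual[i, ]])
  n_cred <- vapply(credited, length, integer(1))
  any_pos <- rowSums(pos & covered) > 0
  status <- ifelse(n_cred == 0, "DISCARDED",
                   ifelse(n_cred == 1, "ASSIGNED", "ASSIGNED_MULTI"))
  reason <- ifelse(n_cred > 0, "NONE",
                   ifelse(any_pos, "ALL_CANDIDATES_DETECTED", "NO_CANDIDATE"))
  tibble::tibble(
    minute_start = active$minute_start,
    rot_total = active$rot_total,
    active_seconds = active$active_seconds,
    credited = credited,
    n_credited = n_cred,
    status = status,
    reason = reason
  )
}

empty_assignments <- function() {
  tibble::tibble(minute_start = ms_to_posix(numeric(0)), rot_total = integer(0),
                 active_seconds = numeric(0), credited = list(),
                 n_credited = integer(0), status = character(0),
                 reason = character(0))
}

#' Summarize discarded wheel-active minutes by reason
#'
#' Discards are expected in practice: animals moving the wheel from outside
#' while detected next to it, or artificial rotations caused by humans
#' cleaning or moving the cage. This report totals the discarded minutes and
#' rotations per reason code so they can be inspected rather than silently
#' lost.
#'
#' @param results Assignment tibble from [assign_ve()].
#' @return A tibble with one row per reason code (`NO_CANDIDATE`,
#'   `ALL_CANDIDATES_DETECTED`), zero-filled, with `minutes` and
#'   `rotations` columns, plus a `TOTAL` row.
#' @export
discard_report <- function(results) {
  codes <- c("NO_CANDIDATE", "ALL_CANDIDATES_DETECTED")
  disc <- results[results$status == "DISCARDED", , drop = FALSE]
  per <- lapply(codes, function(code) {
    sel <- disc$reason == code
    tibble::tibble(reason = code, minutes = sum(sel),
                   rotations = sum(disc$rot_total[sel]))
  })
  per <- dplyr::bind_rows(per)
  dplyr::bind_rows(per, tibble::tibble(reason = "TOTAL",
                                       minutes = sum(per$minutes),
                                       rotations = sum(per$rotations)))
}
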