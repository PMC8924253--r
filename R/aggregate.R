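# Vectorized deduplicated field-change counting over contiguous windows.
# `breaks` are window starts in ms; windows are half-open [b_k, b_{k+1}).
# Returns a matrix [window x animal]. Equals field_changes() applied per
# window (same carry semantics); kept vectorized because summaries touch
# hundreds of windows.
fc_by_window <- function(events, animals, breaks_ms, carry_state = FALSE) {
  nb <- length(breaks_ms) - 1L
  out <- matrix(0L, nrow = nb, ncol = length(animals),
                dimnames = list(NULL, animals))
  ins <- events[events$direction == "IN", , drop = FALSE]
  for (j in seq_along(animals)) {
    ev <- ins[ins$animal_id == animals[[j]], , drop = FALSE]
    if (nrow(ev) < 2) next
    ts <- posix_to_ms(ev$timestamp)
    ant <- ev$antenna
    changed <- ant[-1] != ant[-length(ant)]
    w_later <- findInterval(ts[-1], breaks_ms)
    ok <- changed & w_later >= 1 & w_later <= nb
    if (!carry_state) {
      w_earlier <- findInterval(ts[-length(ts)], breaks_ms)
      ok <- ok & w_earlier == w_later
    }
    if (any(ok)) {
      tab <- tabulate(w_later[ok], nbins = nb)
      out[, j] <- tab
    }
  }
  out
}

window_grid <- function(range, step_ms) {
  r <- posix_to_ms(as.POSIXct(range, tz = scave_tz))
  from <- floor(r[1] / step_ms) * step_ms
  to <- ceiling(r[2] / step_ms) * step_ms
  if (to <= from) to <- from + step_ms
  seq(from, to, by = step_ms)
}

#' Per-animal per-hour activity summary
#'
#' The method's main result surface: for every animal and clock hour in the
#' covered range, the deduplicated field-change count (spontaneous cage
#' activity) together with the wheel rotations credited to the animal and
#' its seconds of wheel movement. The grid is zero-filled: every
#' `(animal, hour)` pair appears exactly once.
#'
#' @param events SCA event tibble.
#' @param assignments Optional assignment tibble from [assign_ve()]; when
#'   `NULL` the wheel columns are zero.
#' @param animals Animal ids to summarize; default all ids in `events`.
#' @param range Length-2 POSIXct range to cover; default the event range.
#' @param carry_state Passed to the field-change counter: whether a crossing
#'   straddling an hour boundary is counted in the later hour (see
#'   [field_changes()]).
#' @return A tibble with columns `animal_id`, `hour_start`, `field_changes`,
#'   `rotations_credited`, `wheel_active_seconds`.
#' @export
hourly_table <- function(events, assignments = NULL, animals = NULL,
                         range = NULL, carry_state = FALSE) {
  if (is.null(animals)) animals <- sort(unique(events$animal_id))
  if (is.null(range)) {
    if (nrow(events) == 0) stop("no events and no explicit range", call. = FALSE)
    range <- range(events$timestamp)
  }
  breaks <- window_grid(range, 3600000)
  fc <- fc_by_window(events, animals, breaks, carry_state)
  hours <- ms_to_posix(breaks[-length(breaks)])
  grid <- tidyr::expand_grid(animal_id = animals, hour_start = hours)
  grid <- grid[order(grid$animal_id, grid$hour_start), ]
  grid$field_changes <- as.integer(fc[cbind(match(posix_to_ms(grid$hour_start),
                                                  breaks[-length(breaks)]),
                                            match(grid$animal_id, animals))])
  grid$rotations_credited <- 0L
  grid$wheel_active_seconds <- 0
  if (!is.null(assignments) && nrow(assignments) > 0) {
    cred <- tidyr::unnest(
      assignments[assignments$n_credited > 0,
                  c("minute_start", "rot_total", "active_seconds", "credited")],
      cols = "credited")
    cred$hour_start <- floor_hour(cred$minute_start)
    agg <- dplyr::summarise(
      dplyr::group_by(cred, .data$credited, .data$hour_start),
      rot = sum(.data$rot_total), secs = sum(.data$active_seconds),
      .groups = "drop")
    m <- match(paste(grid$animal_id, posix_to_ms(grid$hour_start)),
               paste(agg$credited, posix_to_ms(agg$hour_start)))
    hit <- !is.na(m)
    grid$rotations_credited[hit] <- as.integer(agg$rot[m[hit]])
    grid$wheel_active_seconds[hit] <- agg$secs[m[hit]]
  }
  grid
}

#' Daily field-change series (fc / 24 h)
#'
#' Sums the hourly field-change counts over 24-hour windows aligned to a
#' configurable day boundary — midnight by default, or light onset (6 a.m.
#' in the reference 12 h/12 h schedule) for circadian work.
#'
#' @inheritParams hourly_table
#' @param day_boundary_hour Clock hour (0-23) at which a "day" starts.
#' @return A tibble with columns `animal_id`, `day_start`, `field_changes`.
#' @export
daily_fc <- function(events, animals = NULL, range = NULL,
                     day_boundary_hour = 0, carry_state = FALSE) {
  hourly <- hourly_table(events, NULL, animals, range, carry_state)
  shift <- day_boundary_hour * 3600000
  day_ms <- (posix_to_ms(hourly$hour_start) - shift) %/% 86400000 * 86400000 + shift
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(animal_id = hourly$animal_id,
                                   day_start = ms_to_posix(day_ms),
                                   fc = hourly$field_changes),
                    .data$animal_id, .data$day_start),
    field_changes = sum(.data$fc), .groups = "drop")
}

#' Circadian activity profile (percent of daily field changes per hour)
#'
#' For each animal and clock hour 0-23, the share of that hour in the
#' animal's total daily field changes, averaged over days. Rodents housed on
#' a 12 h/12 h dark-light schedule concentrate activity in the dark phase;
#' this profile is the standard way to display it. Days with zero activity
#' are excluded with a warning (a share is undefined for them). For any
#' animal with at least one field change the 24 values sum to 100.
#'
#' @inheritParams hourly_table
#' @return A tibble with columns `animal_id`, `hour` (0-23), `percent`, and
#'   attribute `"n_days"` (days averaged per animal).
#' @seealso [plot_circadian_profile()]
#' @export
circadian_profile <- function(events, animals = NULL, range = NULL,
                              carry_state = FALSE) {
  hourly <- hourly_table(events, NULL, animals, range, carry_state)
  hourly$day <- posix_to_ms(hourly$hour_start) %/% 86400000
  hourly$hour <- as.integer((posix_to_ms(hourly$hour_start) %/% 3600000) %% 24)
  totals <- dplyr::summarise(dplyr::group_by(hourly, .data$animal_id, .data$day),
                             total = sum(.data$field_changes), .groups = "drop")
  zero <- totals$total == 0
  if (any(zero)) {
    warning(sum(zero), " animal-day(s) with zero activity excluded from profile",
            call. = FALSE)
  }
  keep <- totals[!zero, , drop = FALSE]
  hourly <- dplyr::inner_join(hourly, keep, by = c("animal_id", "day"))
  hourly$share <- 100 * hourly$field_changes / hourly$total
  prof <- dplyr::summarise(dplyr::group_by(hourly, .data$animal_id, .data$hour),
                           percent = mean(.data$share), .groups = "drop")
  ndays <- dplyr::summarise(dplyr::group_by(keep, .data$animal_id),
                            n_days = dplyr::n(), .groups = "drop")
  attr(prof, "n_days") <- ndays
  prof
}

#' Group mean and SEM of a per-animal statistic
#'
#' Means and standard errors are computed over animals (not days), the usual
#' unit of replication for cage studies.
#'
#' @param x Tibble with an `animal_id` column and one numeric value column.
#' @param groups Named character vector mapping `animal_id` to group label.
#' @param value Name of the value column.
#' @return Tibble with `group`, `mean`, `sem`, `n`.
#' @export
group_summary <- function(x, groups, value) {
  per_animal <- dplyr::summarise(dplyr::group_by(x, .data$animal_id),
                                 v = mean(.data[[value]]), .groups = "drop")
  per_animal$group <- unname(groups[per_animal$animal_id])
  dplyr::summarise(dplyr::group_by(per_animal, .data$group),
                   mean = mean(.data$v),
                   sem = stats::sd(.data$v) / sqrt(dplyr::n()),
                   n = dplyr::n(), .groups = "drop")
}

#' One-way ANOVA between groups (convenience wrapper)
#'
#' Thin wrapper over [stats::aov()] comparing a per-animal statistic between
#' groups; provided for parity with the usual analysis of such experiments,
#' not part of the attribution method itself.
#'
#' @inheritParams group_summary
#' @return The fitted `aov` object.
#' @export
compare_groups <- function(x, groups, value) {
  per_animal <- dplyr::summarise(dplyr::group_by(x, .data$animal_id),
                                 v = mean(.data[[value]]), .groups = "drop")
  per_animal$group <- factor(unname(groups[per_animal$animal_id]))
  stats::aov(v ~ group, data = per_animal)
}

#' Plot circadian activity profiles
#'
#' Line plot of percent-of-daily-activity per clock hour, one line per
#' animal (or per group if a mapping is supplied), with the dark phase
#' shaded.
#'
#' @param profile Output of [circadian_profile()].
#' @param groups Optional named character vector mapping animal ids to group
#'   labels; profiles are then averaged within group.
#' @param light_on,light_off Clock hours of lights-on/off used for shading.
#' @return A ggplot object.
#' @export
plot_circadian_profile <- function(profile, groups = NULL,
                                   light_on = 6, light_off = 18) {
  df <- profile
  if (!is.null(groups)) {
    df$label <- unname(groups[df$animal_id])
    df <- dplyr::summarise(dplyr::group_by(df, .data$label, .data$hour),
                           percent = mean(.data$percent), .groups = "drop")
  } else {
    df$label <- df$animal_id
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$percent,
                                   colour = .data$label)) +
    ggplot2::annotate("rect", xmin = -0.5, xmax = light_on - 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::annotate("rect", xmin = light_off - 0.5, xmax = 23.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = seq(0, 23, 3)) +
    ggplot2::labs(x = "Clock hour", y = "Field changes [% of daily total]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
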