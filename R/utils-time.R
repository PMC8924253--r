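# Internal time helpers. All timestamps in the package are naive local clock
# times represented as POSIXct in UTC (no DST, no offsets) at millisecond
# resolution.

#' @keywords internal
#' @noRd
scave_tz <- "UTC"

# POSIXct from ms-since-epoch, exact to the millisecond
ms_to_posix <- function(ms) {
  as.POSIXct(ms / 1000, origin = "1970-01-01", tz = scave_tz)
}

# ms-since-epoch (numeric, integral) from POSIXct; rounds to nearest ms so
# that formatting/parsing round-trips are exact
posix_to_ms <- function(t) {
  round(as.numeric(t) * 1000)
}

# snap a POSIXct to exact millisecond grid
round_ms <- function(t) {
  ms_to_posix(posix_to_ms(t))
}

# parse "DD.MM.YYYY" or "YYYY-MM-DD" dates plus "HH:MM:SS(.mmm)" times
parse_date_time_cols <- function(date, time) {
  date <- trimws(as.character(date))
  time <- trimws(as.character(time))
  time <- ifelse(grepl("^\\d{1,2}:\\d{2}$", time), paste0(time, ":00"), time)
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", date)
  de  <- grepl("^\\d{1,2}\\.\\d{1,2}\\.\\d{4}$", date)
  out <- rep(NA_real_, length(date))
  fmt_one <- function(d, fmt, tm) {
    as.POSIXct(paste(d, tm), format = paste(fmt, "%H:%M:%OS"), tz = scave_tz)
  }
  if (any(iso)) out[iso] <- as.numeric(fmt_one(date[iso], "%Y-%m-%d", time[iso]))
  if (any(de))  out[de]  <- as.numeric(fmt_one(date[de], "%d.%m.%Y", time[de]))
  round_ms(as.POSIXct(out, origin = "1970-01-01", tz = scave_tz))
}

# parse a full datetime string in any of the accepted layouts
parse_datetime_any <- function(x) {
  x <- trimws(as.character(x))
  sp <- regexpr("[ T]", x)
  d <- ifelse(sp > 0, substr(x, 1, sp - 1), x)
  t <- ifelse(sp > 0, substring(x, sp + 1), "00:00:00")
  parse_date_time_cols(d, t)
}

# date/time formatting goes through the integer-ms representation so that a
# write/read cycle is exact (format %OS3 truncates, it does not round)
fmt_date <- function(t, dialect) {
  d <- as.Date(posix_to_ms(t) %/% 86400000, origin = "1970-01-01")
  format(d, if (dialect == "de") "%d.%m.%Y" else "%Y-%m-%d")
}

fmt_time <- function(t) {
  ms <- posix_to_ms(t)
  s <- (ms %/% 1000) %% 86400
  sprintf("%02d:%02d:%02d.%03d", s %/% 3600, (s %/% 60) %% 60, s %% 60, ms %% 1000)
}

fmt_datetime <- function(t, dialect, seconds = TRUE) {
  if (seconds) paste(fmt_date(t, dialect), fmt_time(t)) else
    paste(fmt_date(t, dialect), format(t, "%H:%M", tz = scave_tz))
}

# truncate to minute / hour starts (POSIXct in, POSIXct out)
floor_minute <- function(t) ms_to_posix(floor(posix_to_ms(t) / 60000) * 60000)
floor_hour   <- function(t) ms_to_posix(floor(posix_to_ms(t) / 3600000) * 3600000)
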