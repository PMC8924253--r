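#' Read an antenna-event (SCA) export table
#'
#' Reads the CSV table exported by the RFID antenna-grid tracking software:
#' one row per detection change, giving the timestamp, cage, animal RFID,
#' antenna label (1-6), whether the field was entered (`IN`) or left (`OUT`),
#' and on `OUT` rows the dwell time on the antenna in milliseconds (`MS`).
#'
#' Two CSV dialects are understood: `"intl"` (comma separator, dot decimal)
#' and `"de"` (semicolon separator, comma decimal, `DD.MM.YYYY` dates), with
#' `"auto"` detecting the dialect from the header line. Column names are
#' matched case-insensitively and ignoring whitespace; both `Enter` and
#' `ENTER` spellings map to the direction column. Timestamps are kept at
#' millisecond resolution as naive local clock times.
#'
#' @param path Path to the exported CSV file.
#' @param dialect `"auto"` (default), `"intl"` or `"de"`.
#' @param strict If `TRUE` (default) any unparseable row aborts with its line
#'   number; if `FALSE` bad rows are dropped with a warning.
#' @return A tibble of events in file order with columns `timestamp`
#'   (POSIXct, ms resolution), `cage_id`, `animal_id`, `antenna` (integer),
#'   `direction` (`"IN"`/`"OUT"`) and `dwell_ms` (integer, `NA` on `IN` rows).
#' @seealso [write_sca()], [build_occupancy()], [field_changes()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_sca(demo_events(), f)
#' read_sca(f)
read_sca <- function(path, dialect = c("auto", "intl", "de"), strict = TRUE) {
  dialect <- resolve_dialect(path, match.arg(dialect))
  raw <- read_dialect(path, dialect)
  cols <- normalize_names(names(raw))
  need <- c(date = "date", time = "time", cage = "cage", animal = "animal",
            antenna = "antenna", enter = "enter", ms = "ms")
  idx <- stats::setNames(match(need, cols), names(need))
  if (anyNA(idx)) {
    stop("SCA file ", path, " is missing mandatory column(s): ",
         paste(names(need)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_events())

  ts <- parse_date_time_cols(raw[[idx[["date"]]]], raw[[idx[["time"]]]])
  antenna <- suppressWarnings(as.integer(trimws(as.character(raw[[idx[["antenna"]]]]))))
  direction <- toupper(trimws(as.character(raw[[idx[["enter"]]]])))
  bad <- is.na(ts) | is.na(antenna) | !antenna %in% 1:6 | !direction %in% c("IN", "OUT")
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    if (strict) {
      stop("unparseable SCA row(s) at line(s) ", paste(utils::head(lines, 5), collapse = ", "),
           if (sum(bad) > 5) " ..." else "", " of ", path, call. = FALSE)
    }
    warning(sum(bad), " unparseable SCA row(s) skipped (lines ",
            paste(utils::head(lines, 5), collapse = ", "),
            if (sum(bad) > 5) " ..." else "", ")", call. = FALSE)
  }
  dwell <- suppressWarnings(as.numeric(gsub(",", ".", as.character(raw[[idx[["ms"]]]]))))
  dwell <- ifelse(direction == "OUT", as.integer(round(dwell)), NA_integer_)
  out <- tibble::tibble(
    timestamp = ts,
    cage_id = as.character(raw[[idx[["cage"]]]]),
    animal_id = as.character(raw[[idx[["animal"]]]]),
    antenna = antenna,
    direction = direction,
    dwell_ms = dwell
  )
  out[!bad, , drop = FALSE]
}

#' Write an antenna-event table
#'
#' Inverse of [read_sca()]: writes events in the instrument export layout so
#' that re-reading reproduces the input exactly.
#'
#' @param events Event tibble as returned by [read_sca()] or
#'   [simulate_cage()].
#' @param path Output file path.
#' @param dialect `"intl"` (comma separator, ISO dates; default) or `"de"`
#'   (semicolon separator, `DD.MM.YYYY` dates, decimal comma).
#' @return `path`, invisibly.
#' @export
write_sca <- function(events, path, dialect = c("intl", "de")) {
  dialect <- match.arg(dialect)
  stopifnot(all(c("timestamp", "cage_id", "animal_id", "antenna", "direction") %in% names(events)))
  df <- data.frame(
    Date = fmt_date(events$timestamp, dialect),
    Time = fmt_time(events$timestamp),
    CAGE = events$cage_id,
    ANIMAL = events$animal_id,
    Antenna = events$antenna,
    Enter = events$direction,
    MS = ifelse(is.na(events$dwell_ms), "", format(events$dwell_ms, scientific = FALSE, trim = TRUE)),
    check.names = FALSE
  )
  write_dialect(df, path, dialect)
  invisible(path)
}

#' Read a running-wheel (VE) export table
#'
#' Reads the per-minute wheel export: for every minute the rotations to the
#' right and left, their sum, the seconds of wheel movement (`Sum Time`), the
#' number of distinct runs (`Sum Runs`), maximum and average speed in
#' rotations per minute, and the longest run length in seconds (`MaxLen`).
#' The first column is taken as the minute timestamp and may carry any
#' header name, in any of the accepted date layouts.
#'
#' @inheritParams read_sca
#' @return A tibble with columns `minute_start` (POSIXct), `rot_right`,
#'   `rot_left`, `rot_total`, `active_seconds`, `run_count`,
#'   `max_speed_rpm`, `avg_speed_rpm`, `max_run_len_s` and a logical
#'   `active` flag (`FALSE` where no rotation and no movement time was
#'   recorded).
#' @seealso [write_ve()], [assign_ve()]
#' @export
read_ve <- function(path, dialect = c("auto", "intl", "de"), strict = TRUE) {
  dialect <- resolve_dialect(path, match.arg(dialect))
  raw <- read_dialect(path, dialect)
  cols <- normalize_names(names(raw))
  need <- c(right = "right", left = "left", sumtime = "sumtime",
            sumruns = "sumruns", maxspeed = "maxspeed", avgspeed = "avgspeed",
            maxlen = "maxlen")
  idx <- stats::setNames(match(need, cols), names(need))
  if (anyNA(idx)) {
    stop("VE file ", path, " is missing mandatory column(s): ",
         paste(names(need)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_ve())
  minute <- parse_datetime_any(raw[[1]])
  num <- function(key) {
    x <- raw[[idx[[key]]]]
    if (is.character(x)) x <- gsub(",", ".", trimws(x))
    suppressWarnings(as.numeric(x))
  }
  right <- num("right"); left <- num("left")
  bad <- is.na(minute) | is.na(right) | is.na(left)
  if (any(bad)) {
    lines <- which(bad) + 1L
    if (strict) {
      stop("unparseable VE row(s) at line(s) ", paste(utils::head(lines, 5), collapse = ", "),
           " of ", path, call. = FALSE)
    }
    warning(sum(bad), " unparseable VE row(s) skipped", call. = FALSE)
  }
  out <- tibble::tibble(
    minute_start = floor_minute(minute),
    rot_right = as.integer(right),
    rot_left = as.integer(left),
    rot_total = as.integer(right + left),
    active_seconds = num("sumtime"),
    run_count = as.integer(num("sumruns")),
    max_speed_rpm = num("maxspeed"),
    avg_speed_rpm = num("avgspeed"),
    max_run_len_s = num("maxlen")
  )
  out$active <- out$rot_total > 0 | out$active_seconds > 0
  out <- out[!bad, , drop = FALSE]
  sumcol <- which(cols == "sumr+l")
  if (length(sumcol) == 1) {
    decl <- suppressWarnings(as.numeric(gsub(",", ".", as.character(raw[!bad, sumcol]))))
    if (any(decl != out$rot_total, na.rm = TRUE)) {
      warning("Sum R+L column disagrees with Right+Left on ",
              sum(decl != out$rot_total, na.rm = TRUE), " row(s); using Right+Left",
              call. = FALSE)
    }
  }
  if (is.unsorted(out$minute_start, strictly = TRUE)) {
    stop("VE minutes in ", path, " are not strictly increasing", call. = FALSE)
  }
  out
}

#' Write a running-wheel table
#'
#' Inverse of [read_ve()]; re-reading the file reproduces the input records.
#'
#' @param records VE tibble as returned by [read_ve()] or [simulate_cage()].
#' @inheritParams write_sca
#' @return `path`, invisibly.
#' @export
write_ve <- function(records, path, dialect = c("intl", "de")) {
  dialect <- match.arg(dialect)
  df <- data.frame(
    Time = fmt_datetime(records$minute_start, dialect),
    Right = records$rot_right,
    Left = records$rot_left,
    `Sum R+L` = records$rot_total,
    `Sum Time` = records$active_seconds,
    `Sum Runs` = records$run_count,
    MaxSpeed = records$max_speed_rpm,
    AvgSpeed = records$avg_speed_rpm,
    MaxLen = records$max_run_len_s,
    check.names = FALSE
  )
  write_dialect(df, path, dialect)
  invisible(path)
}

#' Write a tidy result table
#'
#' Writes any of the package's result tibbles (assignment results, hourly
#' summaries, daily series, circadian profiles) as a flat CSV. Timestamp
#' columns are formatted in the chosen dialect and list-columns of animal ids
#' (`credited`) are semicolon-joined. [read_results()] restores the original
#' column types.
#'
#' @param x A result tibble.
#' @inheritParams write_sca
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, dialect = c("intl", "de")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  for (nm in names(df)) {
    col <- df[[nm]]
    if (inherits(col, "POSIXct")) {
      df[[nm]] <- fmt_datetime(col, dialect)
    } else if (is.list(col)) {
      df[[nm]] <- vapply(col, paste, character(1), collapse = ";")
    }
  }
  write_dialect(df, path, dialect)
  invisible(path)
}

#' Read back a tidy result table written by [write_results()]
#'
#' @inheritParams read_sca
#' @return A tibble with timestamp columns (`*_start`, `timestamp`) parsed to
#'   POSIXct and the `credited` column restored to a list of animal-id
#'   vectors.
#' @export
read_results <- function(path, dialect = c("auto", "intl", "de")) {
  dialect <- resolve_dialect(path, match.arg(dialect))
  raw <- read_dialect(path, dialect)
  out <- tibble::as_tibble(raw)
  for (nm in names(out)) {
    if (grepl("(_start$|^timestamp$)", nm)) {
      out[[nm]] <- parse_datetime_any(out[[nm]])
    } else if (nm == "credited") {
      out[[nm]] <- lapply(strsplit(as.character(out[[nm]]), ";", fixed = TRUE),
                          function(v) v[nzchar(v)])
    }
  }
  out
}

# ---- dialect plumbing -------------------------------------------------------

resolve_dialect <- function(path, dialect) {
  if (dialect != "auto") return(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0) return("intl")
  if (grepl(";", header, fixed = TRUE)) "de" else "intl"
}

read_dialect <- function(path, dialect) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, check.names = FALSE,
                    sep = if (dialect == "de") ";" else ",",
                    dec = if (dialect == "de") "," else ".",
                    colClasses = "character", quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE,
                    blank.lines.skip = TRUE)
}

write_dialect <- function(df, path, dialect) {
  num <- vapply(df, is.numeric, logical(1))
  for (nm in names(df)[num]) {
    v <- format(df[[nm]], scientific = FALSE, trim = TRUE, nsmall = 0,
                drop0trailing = TRUE)
    if (dialect == "de") v <- sub(".", ",", v, fixed = TRUE)
    v[is.na(df[[nm]])] <- ""
    df[[nm]] <- v
  }
  utils::write.table(df, path, sep = if (dialect == "de") ";" else ",",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

normalize_names <- function(x) {
  tolower(gsub("[[:space:]_.]", "", x))
}

empty_events <- function() {
  tibble::tibble(timestamp = ms_to_posix(numeric(0)), cage_id = character(0),
                 animal_id = character(0), antenna = integer(0),
                 direction = character(0), dwell_ms = integer(0))
}

empty_ve <- function() {
  tibble::tibble(minute_start = ms_to_posix(numeric(0)), rot_right = integer(0),
                 rot_left = integer(0), rot_total = integer(0),
                 active_seconds = numeric(0), run_count = integer(0),
                 max_speed_rpm = numeric(0), avg_speed_rpm = numeric(0),
                 max_run_len_s = numeric(0), active = logical(0))
}

#' A minimal example antenna-event table
#'
#' Ten hand-written events for two animals crossing a few antennas; used in
#' documentation examples.
#'
#' @return An event tibble in the layout of [read_sca()].
#' @export
demo_events <- function() {
  t0 <- as.POSIXct("2022-01-10 08:00:00", tz = "UTC")
  tibble::tibble(
    timestamp = t0 + c(0, 4.2, 4.25, 9, 9.1, 30, 31, 31.05, 40, 41),
    cage_id = "1",
    animal_id = rep(c("A", "B"), each = 5),
    antenna = c(4L, 4L, 2L, 2L, 1L, 3L, 3L, 6L, 6L, 5L),
    direction = c("IN", "OUT", "IN", "OUT", "IN", "IN", "OUT", "IN", "OUT", "IN"),
    dwell_ms = c(NA, 4200L, NA, 4750L, NA, NA, 1000L, NA, 8950L, NA)
  )
}
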