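t0 <- as.POSIXct("2022-01-10 08:00:00", tz = "UTC")

mk_events <- function(offsets, animals, antennas, dirs) {
  tibble::tibble(timestamp = t0 + offsets, cage_id = "1",
                 animal_id = animals, antenna = as.integer(antennas),
                 direction = dirs,
                 dwell_ms = ifelse(dirs == "OUT", 1L, NA_integer_))
}

test_that("an IN/OUT pair closes one interval", {
  ev <- mk_events(c(0, 5), c("A", "A"), c(1, 1), c("IN", "OUT"))
  iv <- build_occupancy(ev)
  expect_equal(nrow(iv), 1)
  expect_equal(as.numeric(iv$end - iv$start, units = "secs"), 5)
  expect_equal(iv$antenna, 1L)
})

test_that("a doubling overlap across antennas is retained, not an error", {
  ev <- mk_events(c(0, 3, 4, 9), rep("A", 4), c(1, 2, 1, 2),
                  c("IN", "IN", "OUT", "OUT"))
  iv <- build_occupancy(ev)
  expect_equal(nrow(iv), 2)
  iv <- iv[order(iv$antenna), ]
  expect_equal(as.numeric(iv$start - t0, units = "secs"), c(0, 3))
  expect_equal(as.numeric(iv$end - t0, units = "secs"), c(4, 9))
})

test_that("unmatched OUT and repeated IN are skipped with a warning, error in strict mode", {
  ev <- mk_events(c(0, 1, 2, 3), rep("A", 4), c(1, 1, 2, 2),
                  c("OUT", "IN", "IN", "IN"))
  expect_warning(iv <- build_occupancy(ev), "anomalous")
  expect_equal(nrow(iv), 2)  # two open intervals on antennas 1 and 2
  expect_true(all(is.na(iv$end)))
  expect_error(build_occupancy(ev, strict = TRUE), "anomalous")
})

test_that("occupancy equals a per-millisecond counting oracle on random streams", {
  set.seed(42)
  for (rep in 1:25) {
    ev <- rand_stream(200)
    iv <- build_occupancy(ev)
    span <- round(as.numeric(range(ev$timestamp)) * 1000)
    ticks <- seq(span[1] - 5, span[2] + 5)
    for (a in unique(ev$animal_id)) {
      for (x in unique(ev$antenna[ev$animal_id == a])) {
        expect_identical(interval_occupied(iv, a, x, ticks),
                         brute_occupied(ev, a, x, ticks),
                         label = paste("rep", rep, a, x))
      }
    }
  }
})

test_that("field change counting matches the Fig-style examples", {
  ev <- mk_events(c(0, 10, 10.5, 20), rep("A", 4), c(4, 4, 2, 2),
                  c("IN", "OUT", "IN", "OUT"))
  expect_equal(field_changes(ev, "A", c(t0, t0 + 60)), 1L)   # 4 -> 2
  one <- mk_events(0, "A", 3, "IN")
  expect_equal(field_changes(one, "A", c(t0, t0 + 60)), 0L)  # no pair
  seq5 <- mk_events(0:4, rep("A", 5), c(1, 1, 2, 2, 1), rep("IN", 5))
  expect_equal(field_changes(seq5, "A", c(t0, t0 + 60)), 2L) # 1->2->1
})

test_that("field changes ignore OUT rows entirely and match the rle oracle", {
  set.seed(7)
  for (rep in 1:30) {
    ev <- rand_stream(60)
    w <- range(ev$timestamp) + c(-1, 1)
    for (a in unique(ev$animal_id)) {
      fc <- field_changes(ev, a, w)
      expect_identical(fc, naive_field_changes(ev, a, w))
      # removing all OUT rows changes nothing
      expect_identical(field_changes(ev[ev$direction == "IN", ], a, w), fc)
      # inserting extra OUT rows changes nothing
      extra <- ev[sample(nrow(ev), 10), ]
      extra$direction <- "OUT"
      aug <- dplyr::arrange(dplyr::bind_rows(ev, extra), timestamp)
      expect_identical(field_changes(aug, a, w), fc)
    }
  }
})

test_that("with carry_state, counts over a partition sum to the whole-window count", {
  set.seed(13)
  for (rep in 1:10) {
    ev <- rand_stream(120)
    tmin <- min(ev$timestamp); tmax <- max(ev$timestamp) + 0.001
    cuts <- sort(c(tmin, tmin + stats::runif(3) * as.numeric(tmax - tmin, units = "secs"), tmax))
    for (a in unique(ev$animal_id)) {
      whole <- field_changes(ev, a, c(tmin, tmax), carry_state = TRUE)
      parts <- sum(vapply(seq_len(4), function(i) {
        field_changes(ev, a, c(cuts[i], cuts[i + 1]), carry_state = TRUE)
      }, integer(1)))
      expect_identical(parts, whole)
      # without carry the parts can only lose boundary pairs
      parts0 <- sum(vapply(seq_len(4), function(i) {
        field_changes(ev, a, c(cuts[i], cuts[i + 1]))
      }, integer(1)))
      expect_lte(parts0, whole)
    }
  }
})

test_that("unknown animals count zero with a warning", {
  ev <- mk_events(0, "A", 1, "IN")
  expect_warning(fc <- field_changes(ev, "ZZ", c(t0, t0 + 60)), "no events")
  expect_identical(fc, 0L)
})

test_that("detection state distinguishes resting, wheel and never-seen animals", {
  ev <- mk_events(c(0, 10, 10.2, 60), c("C", "A", "A", "A"), c(1, 2, 2, 2),
                  c("IN", "IN", "OUT", "IN"))
  iv <- build_occupancy(ev)
  resting <- detection_state(iv, "C", t0 + 30)
  expect_true(resting$detected)
  in_wheel <- detection_state(iv, "A", t0 + 30)
  expect_false(in_wheel$detected)
  expect_equal(in_wheel$last_closed_antenna, 2L)
  before <- detection_state(iv, "C", t0 - 5)
  expect_false(before$detected)
  expect_true(is.na(before$last_closed_antenna))
})

test_that("last_closed_antenna breaks end ties by the later start", {
  ev <- mk_events(c(0, 5, 8, 8), rep("A", 4), c(3, 1, 3, 1),
                  c("IN", "IN", "OUT", "OUT"))
  st <- detection_state(build_occupancy(ev), "A", t0 + 10)
  expect_equal(st$last_closed_antenna, 1L)
})
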