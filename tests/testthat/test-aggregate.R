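t0 <- as.POSIXct("2022-01-10 00:00:00", tz = "UTC")

test_that("an empty hour is zero-filled, one row per animal-hour", {
  ev <- tibble::tibble(timestamp = t0, cage_id = "1", animal_id = "A",
                       antenna = 1L, direction = "IN", dwell_ms = NA_integer_)
  hr <- hourly_table(ev, animals = "A", range = c(t0, t0 + 3600))
  expect_equal(nrow(hr), 1)
  expect_equal(hr$field_changes, 0L)
  expect_equal(hr$rotations_credited, 0L)
})

test_that("the scenario-A hour credits A with the rotations and counts crossings", {
  sc <- make_scenario("A")
  res <- assign_ve(sc$events, sc$ve, coverage = sc$coverage)
  hr <- hourly_table(sc$events, res, range = sc$coverage)
  get <- function(a, col) hr[[col]][hr$animal_id == a]
  expect_equal(get("A", "field_changes"), 1L)  # 4 -> 2
  expect_equal(get("B", "field_changes"), 0L)
  expect_equal(get("C", "field_changes"), 1L)  # 6 -> 5
  expect_equal(get("A", "rotations_credited"), 25L)
  expect_equal(get("B", "rotations_credited"), 0L)
})

test_that("the hourly grid is complete and matches per-window field_changes", {
  sim <- simulate_cage(sim_config(duration_days = 0.25, seed = 17))
  rng <- sim_coverage(sim)
  for (carry in c(FALSE, TRUE)) {
    hr <- hourly_table(sim$events, animals = sim$config$animal_ids,
                       range = rng, carry_state = carry)
    expect_equal(nrow(hr), 6 * sim$config$n_animals)
    expect_false(any(duplicated(hr[, c("animal_id", "hour_start")])))
    for (i in sample(nrow(hr), 20)) {
      expect_identical(hr$field_changes[i],
                       field_changes(sim$events, hr$animal_id[i],
                                     c(hr$hour_start[i], hr$hour_start[i] + 3600),
                                     carry_state = carry),
                       label = paste("row", i, "carry", carry))
    }
  }
})

test_that("hourly counts summed per day equal the daily series", {
  sim <- simulate_cage(sim_config(duration_days = 2, seed = 19))
  hr <- hourly_table(sim$events, range = sim_coverage(sim))
  daily <- daily_fc(sim$events, range = sim_coverage(sim))
  hr$day <- as.Date(hr$hour_start)
  by_day <- dplyr::summarise(dplyr::group_by(hr, animal_id, day),
                             fc = sum(field_changes), .groups = "drop")
  daily$day <- as.Date(daily$day_start)
  merged <- merge(by_day, daily, by = c("animal_id", "day"))
  expect_equal(nrow(merged), nrow(daily))
  expect_equal(merged$fc, merged$field_changes)
})

test_that("a shifted day boundary regroups the same hourly counts", {
  sim <- simulate_cage(sim_config(duration_days = 1, seed = 23))
  d0 <- daily_fc(sim$events, range = sim_coverage(sim))
  d6 <- daily_fc(sim$events, range = sim_coverage(sim), day_boundary_hour = 6)
  # total field changes are identical however days are cut
  expect_equal(sum(d6$field_changes), sum(d0$field_changes))
  expect_true(all(format(d6$day_start, "%H") == "06"))
})

test_that("circadian percentages sum to 100 per animal", {
  sim <- simulate_cage(sim_config(duration_days = 2, seed = 29))
  prof <- circadian_profile(sim$events, range = sim_coverage(sim))
  sums <- tapply(prof$percent, prof$animal_id, sum)
  expect_equal(as.numeric(sums), rep(100, sim$config$n_animals), tolerance = 1e-9)
})

test_that("a flat movement rate yields a flat profile", {
  cfg <- sim_config(n_animals = 1, duration_days = 4, seed = 37,
                    move_rate_dark = 100, move_rate_light = 100,
                    wheel_bout_rate = 0, p_artifact_minute = 0)
  sim <- simulate_cage(cfg)
  prof <- circadian_profile(sim$events, range = sim_coverage(sim), carry_state = TRUE)
  # 100/24 = 4.17% per hour; hourly counts ~Poisson(100) over 4 days
  expect_true(all(abs(prof$percent - 100 / 24) < 1.5))
})

test_that("zero-activity days are excluded with a warning", {
  ev <- tibble::tibble(timestamp = t0 + 3600, cage_id = "1", animal_id = "A",
                       antenna = 1L, direction = "IN", dwell_ms = NA_integer_)
  expect_warning(
    prof <- circadian_profile(ev, range = c(t0, t0 + 2 * 86400)),
    "zero activity")
  expect_equal(nrow(prof), 0)
})

test_that("group summaries and the ANOVA wrapper run over animals", {
  sim <- simulate_cage(sim_config(duration_days = 1, seed = 41))
  daily <- daily_fc(sim$events, range = sim_coverage(sim))
  groups <- stats::setNames(c("CON", "CON", "EX", "EX"), sim$config$animal_ids)
  gs <- group_summary(daily, groups, "field_changes")
  expect_setequal(gs$group, c("CON", "EX"))
  expect_equal(gs$n, c(2L, 2L))
  fit <- compare_groups(daily, groups, "field_changes")
  expect_s3_class(fit, "aov")
})

test_that("the circadian plot builds without error", {
  sim <- simulate_cage(sim_config(duration_days = 1, seed = 43))
  prof <- circadian_profile(sim$events, range = sim_coverage(sim))
  p <- plot_circadian_profile(prof)
  expect_s3_class(p, "ggplot")
})
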