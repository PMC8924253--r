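test_that("the three canonical scenarios resolve as documented", {
  for (nm in c("A", "B", "C")) {
    sc <- make_scenario(nm)
    res <- assign_ve(sc$events, sc$ve, coverage = sc$coverage)
    expect_equal(nrow(res), 1, label = nm)
    expect_identical(res$credited[[1]], sc$expected$credited, label = nm)
    expect_identical(res$status, sc$expected$status, label = nm)
    expect_identical(res$reason, sc$expected$reason, label = nm)
  }
})

test_that("an all-zero wheel table yields no result rows", {
  sc <- make_scenario("A")
  ve0 <- sc$ve
  ve0$rot_total <- 0L; ve0$rot_right <- 0L
  expect_equal(nrow(assign_ve(sc$events, ve0, coverage = sc$coverage)), 0)
})

test_that("two undetected animals that both last entered wheel antennas are both credited in full", {
  t0 <- as.POSIXct("2022-01-10 14:00:00", tz = "UTC")
  ev <- tibble::tibble(
    timestamp = t0 + c(0, 100, 5, 110, 10),
    cage_id = "1",
    animal_id = c("A", "A", "C", "C", "B"),
    antenna = c(2L, 2L, 1L, 1L, 3L),
    direction = c("IN", "OUT", "IN", "OUT", "IN"),
    dwell_ms = c(NA, 100000L, NA, 105000L, NA)
  )
  ev <- dplyr::arrange(ev, timestamp)
  sc <- make_scenario("A")  # borrow the VE stream (active minute 6)
  res <- assign_ve(ev, sc$ve, coverage = sc$coverage)
  expect_identical(res$status, "ASSIGNED_MULTI")
  expect_identical(res$credited[[1]], c("A", "C"))
  # full rotation count to each animal, not split
  hr <- hourly_table(ev, res, range = sc$coverage)
  expect_equal(hr$rotations_credited[hr$animal_id %in% c("A", "C")],
               rep(res$rot_total, 2))
})

test_that("minutes outside SCA coverage are discarded with a warning", {
  sc <- make_scenario("A")
  expect_warning(res <- assign_ve(sc$events, sc$ve), "coverage")
  # event range ends at A's wheel entry (270 s), before the active minute
  expect_identical(res$status, "DISCARDED")
  expect_identical(res$reason, "NO_CANDIDATE")
})

test_that("whole-minute candidates are a subset of any fractional-strictness candidates", {
  sim <- simulate_cage(sim_config(duration_days = 0.5, seed = 21, p_bystander = 0.2))
  iv <- build_occupancy(sim$events)
  active <- sim$ve$minute_start[sim$ve$rot_total > 0]
  roster <- sim$config$animal_ids
  for (m in active[seq(1, length(active), length.out = min(30, length(active)))]) {
    strict <- candidates(iv, m, wheel_config(strictness = "whole-minute"), roster)
    for (f in c(0.2, 0.5, 0.9)) {
      relaxed <- candidates(iv, m, wheel_config(strictness = f), roster)
      expect_true(all(strict %in% relaxed))
    }
  }
})

test_that("fractional strictness recovers the entry minute of a bout", {
  t0 <- as.POSIXct("2022-01-10 14:00:00", tz = "UTC")
  # A sits on antenna 2 and enters the wheel 10 s into the active minute
  ev <- tibble::tibble(
    timestamp = t0 + c(0, 310, 5),
    cage_id = "1", animal_id = c("A", "A", "B"),
    antenna = c(2L, 2L, 3L), direction = c("IN", "OUT", "IN"),
    dwell_ms = c(NA, 310000L, NA)
  )
  ev <- dplyr::arrange(ev, timestamp)
  sc <- make_scenario("A")
  whole <- assign_ve(ev, sc$ve, wheel_config(), coverage = sc$coverage)
  frac <- assign_ve(ev, sc$ve, wheel_config(strictness = 0.25), coverage = sc$coverage)
  expect_identical(whole$status, "DISCARDED")
  expect_identical(frac$credited[[1]], "A")
})

test_that("max_gap_s excludes animals whose wheel-antenna exit is too old", {
  sc <- make_scenario("A")  # A left antenna 2 at 270 s; active minute starts at 300 s
  tight <- assign_ve(sc$events, sc$ve, wheel_config(max_gap_s = 10), coverage = sc$coverage)
  loose <- assign_ve(sc$events, sc$ve, wheel_config(max_gap_s = 60), coverage = sc$coverage)
  expect_identical(tight$status, "DISCARDED")
  expect_identical(loose$credited[[1]], "A")
})

test_that("rotation totals are conserved between input and results", {
  sim <- simulate_cage(sim_config(duration_days = 1, seed = 9, p_bystander = 0.15,
                                  p_artifact_minute = 0.003))
  res <- assign_ve(sim$events, sim$ve, coverage = sim_coverage(sim))
  expect_identical(sum(res$rot_total), sum(sim$ve$rot_total[sim$ve$rot_total > 0]))
  # credited rotations per animal sum to the k-weighted measured total
  hr <- hourly_table(sim$events, res, range = sim_coverage(sim))
  expect_equal(sum(hr$rotations_credited), sum(res$n_credited * res$rot_total))
})

test_that("discard report totals minutes and rotations per reason", {
  sc <- make_scenario("A")
  res_a <- assign_ve(sc$events, sc$ve, coverage = sc$coverage)
  rep_a <- discard_report(res_a)
  expect_equal(rep_a$minutes, c(0, 0, 0))
  sc_c <- make_scenario("C")
  res_c <- assign_ve(sc_c$events, sc_c$ve, coverage = sc_c$coverage)
  rep_c <- discard_report(res_c)
  expect_equal(rep_c$minutes[rep_c$reason == "ALL_CANDIDATES_DETECTED"], 1)
  expect_equal(rep_c$rotations[rep_c$reason == "TOTAL"], sc_c$ve$rot_total[6])
})

test_that("injected artifact minutes are all discarded", {
  sim <- simulate_cage(sim_config(duration_days = 2, seed = 31,
                                  p_artifact_minute = 0.01))
  res <- assign_ve(sim$events, sim$ve, coverage = sim_coverage(sim))
  tm <- truth_minutes(sim)
  art <- which(tm$artifact & lengths(tm$exercisers) == 0)
  expect_gt(length(art), 0)
  expect_true(all(res$status[art] == "DISCARDED"))
})
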