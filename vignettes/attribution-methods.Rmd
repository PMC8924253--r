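---
title: "Attributing wheel running to individuals in group-housed cages: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing wheel running to individuals in group-housed cages: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaveR)
```

## The measurement problem

Voluntary wheel running in rodents is usually measured by single-housing one
animal per wheel, which is stressful and changes the very behaviour under
study. An alternative keeps 3–4 mice group-housed on an RFID antenna platform:
the cage floor spans a 2×3 grid of detection fields (antennas 1–6), each
animal carries a subcutaneous chip, and the platform logs a row whenever a
chip appears in (`IN`) or disappears from (`OUT`) an antenna field. A running
wheel stands on antennas 1 and 2. The wheel counts rotations per minute but
cannot read chips — and, crucially, an animal *inside* the wheel is out of
range of every antenna, so it disappears from the tracking log entirely.

`scaveR` turns these two anonymous instrument exports into per-animal
measures:

* **spontaneous cage activity (SCA)** — deduplicated antenna *field changes*
  per animal per time window, and
* **voluntary exercise (VE)** — wheel rotations per minute credited to the
  individual animal(s) that were exercising.

## Occupancy intervals and the dedup rule

The event log only records detection changes. Pairing each `IN` with the next
`OUT` on the same `(animal, antenna)` gives half-open occupancy intervals
`[start, end)`; an `IN` without a matching `OUT` leaves an *open* interval
(the animal is still there — or it climbed into the wheel). Because the next
antenna often picks an animal up before the previous one logs its exit
("doubling"), intervals of one animal on *different* antennas may overlap by
some tens to hundreds of milliseconds; this is physics, not an error, and is
retained.

Doubling is also why naively counting log rows overstates locomotion: each
crossing contributes an entry *and* an exit row, interleaved unpredictably.
The field-change count therefore uses `IN` rows only: restrict to an animal's
entries inside a half-open window and count consecutive pairs with different
antenna labels. This makes the count provably invariant to inserting or
removing any number of `OUT` rows, a property the test suite asserts against
an independent run-length-encoding oracle on randomized streams.

Windows are independent by default: a crossing that straddles a window
boundary is counted in neither window. With `carry_state = TRUE` the last
known antenna is carried across the boundary, which makes counts over a
partition of a range sum exactly to the whole-range count. We default to
independent windows (the simpler contract for exported hourly tables) and use
the carrying variant wherever exact additivity with an analytic expectation
matters, e.g. in the rate-recovery validation below.

## The attribution rule

For every wheel-active minute, an animal is credited when over the rotation
interval it

* **(a)** last entered a wheel antenna — its most recent occupancy interval,
  open or closed, started on antenna 1 or 2 — and
* **(b)** was not detected by *any* antenna while the wheel turned.

One qualifying animal: the minute and its full rotation count are assigned to
it. Several (two mice can share a wheel): the full count is credited to
*each*, not split, so per-animal totals remain interpretable as "rotations
this animal produced or co-produced". None: the minute is discarded with a
reason code — `NO_CANDIDATE` when nobody's last entry was a wheel antenna
(e.g. a human moving the cage while the animals sit elsewhere), or
`ALL_CANDIDATES_DETECTED` when animals next to the wheel spun it from outside
while remaining visible to the platform. Discards are a feature: they are the
honest answer for minutes the data cannot disambiguate, and
`discard_report()` totals them for inspection.

Premise (a) deliberately reads "last entered", not "last exited": an animal
*resting on* a wheel antenna (whose interval is still open) has entered a
wheel antenna, fails (b), and is precisely the situation the
`ALL_CANDIDATES_DETECTED` code describes. For an undetected animal — whose
intervals are all closed — "most recent entry" and "most recent exit"
coincide, so the reading only matters for detected bystanders.

### The rotation interval

Wheel exports are per-minute aggregates, so the rotation interval defaults to
the whole minute and premise (b) means "never detected during that minute".
That choice is conservative: the minute in which an animal climbs in (or out)
of the wheel contains a detected stretch, so entry and exit minutes of a bout
are discarded rather than guessed. The fractional alternative,
`wheel_config(strictness = f)`, tolerates detection for up to a fraction `f`
of the minute and recovers such edge minutes at the cost of a small
mis-assignment risk; `max_gap_s` can additionally require the qualifying
wheel-antenna exit to lie within a bounded gap before the minute. The default
keeps `max_gap_s = Inf`, since a temporal bound silently drops long bouts and
premise (a) constrains *which* antenna was last entered, not when.

Minutes outside the time range the tracking platform was recording
(`coverage`, defaulting to the event timestamp range) are discarded with a
warning instead of being attributed from absent evidence.

## Aggregation

`hourly_table()` zero-fills a complete `(animal, hour)` grid with field
changes, credited rotations and wheel-active seconds. `daily_fc()` sums
hourly counts into 24-h windows; the day boundary is midnight by default and
configurable to light onset, the usual alignment in circadian work.
`circadian_profile()` expresses each clock hour as a percentage of the
animal's daily field changes, averaged over days; days with zero activity are
excluded with a warning, and each animal's 24 values sum to 100. Group means
and SEMs are computed over animals, the unit of replication in cage studies;
`compare_groups()` wraps a one-way ANOVA for convenience only. The light
schedule enters only as shading/parameters (`light_on`, `light_off`), never
as a hard-coded constant, because reported transition times vary between
protocols.

## The cage simulator

No public dataset pairs these two instrument exports with known per-minute
exerciser identity, so validation rests on `simulate_cage()`, which generates
both streams *plus* that ground truth from one seed:

* **Movement** is a continuous-time Markov walk on the 2×3 grid
  (jumps to orthogonally adjacent antennas, exponential holding times) with a
  two-level dark/light rate. Defaults: 150 crossings/h (dark), 50/h (light),
  i.e. about 2400 crossings per 24 h at a 3:1 dark:light ratio — the order of
  magnitude home-cage RFID tracking reports for laboratory mice. The model is
  deliberately simple enough that the expected field-change count per window
  is the configured rate, giving an analytic target for recovery tests.
* **Bouts** start, at a phase-dependent rate, only while an animal sits on a
  wheel antenna and the wheel is free; the animal then emits an `OUT` (all of
  its open intervals close — the platform drops the chip at once) and is
  invisible until the bout ends on a wheel antenna. Durations and speeds are
  log-normal (median 2 min, 40 rpm: minutes-long bouts at typical mouse
  running speeds, several thousand rotations per animal-day).
* **Co-exercise**: with probability `p_bystander` a second animal walks to
  the wheel during a bout and climbs in, producing genuinely multi-animal
  minutes. Bystanders that merely *sit* next to the wheel need no parameter —
  the movement model produces them constantly.
* **Doubling**: a configurable fraction of antenna-to-antenna exits is logged
  50–500 ms after the next entry (the magnitude is not documented for the
  real platform; the range just needs to exercise the overlap handling).
* **Artifacts**: with probability `p_artifact_minute` a rotation burst is
  injected into a minute while *no* animal is in the wheel — the
  cage-cleaning/weighing situation — and flagged in the ground truth.

All internal times live on an exact millisecond grid, so the emitted events,
the true position path and the per-minute truth are mutually consistent with
no floating-point edge cases, and a fixed seed reproduces every output byte
for byte.

### What recovery results do and do not show

Under whole-minute strictness the credited set of every minute equals, by
construction, the set of animals inside the wheel for the *entire* minute:
the validation suite asserts this equality minute-by-minute on multi-day
simulations, 100% accuracy on cleanly exercised minutes, discarding of all
artifact minutes, and exact rotation conservation. These are checks that the
*attribution logic* implements its stated rule without leakage — they cannot
certify the rule's physical premises (that an animal in a real wheel is
always invisible, that the platform never misses a crossing, that chips never
collide). The simulator also omits within-antenna activity, sensor dropouts,
clock drift and multi-cage interference; real deployments should expect a
higher discard rate than simulation and should review `discard_report()`
routinely.

### Validation problem sizes

The packaged checks use a 7-day, 4-mouse cage for ground-truth recovery
(≈1,700 cleanly exercised minutes), a 2-day cage with heavy co-exercise and
artifacts for the confounded cases, 1,000 randomized event streams for the
dedup property, per-millisecond replay of streams of up to 500 events for
interval equivalence, and 20 replicate days for recovering the 3:1 dark:light
rate ratio within three Monte-Carlo standard errors — sizes at which the
Monte-Carlo bands are tight while the whole suite stays comfortably
desk-sized.

## File formats and numerical conventions

The instrument exports are German-market software, so both readers accept an
international dialect (comma separator, dot decimal, ISO dates) and a German
one (semicolon, decimal comma, `DD.MM.YYYY`), auto-detected from the header;
column names match case-insensitively and both `Enter`/`ENTER` header
spellings map to the direction column. The wheel export's leading timestamp
column carries no fixed name in the wild, so the first column is parsed as
the minute stamp, with or without seconds. Timestamps are naive local clock
times held at millisecond resolution; writers format milliseconds from the
integer representation so a write/read cycle is exact. `MS` (dwell) values
are meaningful on `OUT` rows only and ignored on `IN` rows. Malformed rows
abort with their line numbers by default; a lenient mode skips them with a
warning. Anomalous event sequences (an exit without a matching entry, a
repeated entry) are logged and skipped, or rejected outright in strict mode —
they indicate chip or platform faults that should be looked at, not silently
repaired.

## Known limitations

* Per-minute wheel aggregation makes bout entry/exit minutes intrinsically
  ambiguous under the whole-minute rule; fractional strictness trades that
  ambiguity against mis-assignment risk.
* Field changes are a surrogate for locomotion: activity within a single
  antenna field is invisible, and no distances or behavioural categories are
  inferred.
* Attribution is deterministic; confounded minutes are discarded, never
  probabilistically split.
* One cage, one wheel: multi-wheel or multi-cage setups are out of scope.
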