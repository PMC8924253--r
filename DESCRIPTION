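Package: scaveR
Title: Individual Attribution of Wheel Running and Cage Activity in
    Group-Housed Rodents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads the event tables exported by RFID antenna-grid home-cage
    tracking platforms and per-minute running-wheel counters, reconstructs
    per-animal antenna occupancy intervals, counts deduplicated antenna field
    changes as a surrogate for spontaneous cage activity, and credits each
    wheel-active minute to the individual animal(s) that last entered a wheel
    antenna and were undetectable while the wheel turned, discarding ambiguous
    or artifactual minutes. Includes hourly, daily and circadian activity
    summaries, a ground-truth cage simulator for validation, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    grDevices,
    optparse,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
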