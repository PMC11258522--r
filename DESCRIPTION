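Package: actirhythm
Title: Nonparametric Rest-Activity Rhythm Analysis for Wrist Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Derive minute-level activity counts from raw tri-axial wrist
    accelerometry (gravity removal, 0.5-3 Hz bandpass, thresholded 2-second
    integration), compute the nonparametric circadian rest-activity rhythm
    indicators (interdaily stability, intradaily variability, M10, L5 and
    relative amplitude), simulate inpatient actigraphy cohorts with a
    controllable diurnal rhythm, day-to-day jitter and rest-activity
    fragmentation, and compare rhythm indicators between groups and against
    clinical scores with rank-based statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
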