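Package: tendonload
Title: Cumulative Achilles Tendon Load from Force-Sensing Insoles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates Achilles tendon load from multi-day, three-channel
    plantar contact-force recordings collected with instrumented insoles,
    and summarises it into cumulative loading biomarkers. Provides quality
    control for baseline drift and erroneous recordings, a moment-arm model
    converting heel/midfoot/forefoot forces to body-weight-normalized tendon
    load, thresholded cumulative impulse and loading-time metrics, a
    day-subsampling reliability analysis (mean absolute percent error,
    Pearson correlation, intraclass correlation), correlation tables against
    clinical and functional measures, and a synthetic cohort generator with
    exact ground-truth bookkeeping for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
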