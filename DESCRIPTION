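Package: ccperiods
Title: Chest-Compression Period Detection from Defibrillator Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects periods of chest compressions in cardiopulmonary
    resuscitation (CPR) recordings directly from the sternal accelerometer
    channel of a defibrillator. The detector band-pass filters the
    acceleration, forms a centered one-second sliding mean of its absolute
    value, soft-shrinks the smoothed derivative of that envelope, locates
    alternating extrema as candidate start/stop markers, filters candidate
    pauses by duration and envelope-ratio rules, and refines markers by a
    derivative-weighted mean. Includes readers and writers for the published
    CSV case layout, chest compression fraction (CCF) and annotation
    agreement metrics, and a seeded synthetic case generator with exact
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
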