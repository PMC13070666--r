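Package: presmat
Title: Posture, Mobility and Pressure-Exposure Analysis for Continuous
    Pressure-Mat Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing continuous interface-pressure recordings
    from bed sensing mats in pressure-injury care. Detects large-scale
    postural changes from the combined derivative of the centre of
    pressure and contact area, segments static postures, anchors a
    buttock region of interest at the per-posture centre of pressure,
    computes peak pressure, peak pressure index and diagonal peak
    pressure gradient signatures, and stratifies each posture into
    low/moderate/high/very-high exposure against sigmoid pressure-time
    injury thresholds. Includes a synthetic pressure-mat session
    generator with ground truth for validation, readers and writers for
    a plain-text frame-stack format, and packaged pre/post-intervention
    cohort tables with reporting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
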