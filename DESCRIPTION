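Package: curltrack
Title: Tracking and Force-Control Analysis for Curl-Field Manual Tracking Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and analyses planar visuo-manual tracking of an
    eight-shaped (Lissajous) target under a curl viscous force field. Provides
    the error-gated target model, an intermittent-control subject simulator
    with arm impedance and tunable feedforward force compensation, kinematic
    smoothing and submovement segmentation, per-lap tracking indicators
    (duration, tracking-error decomposition, figural error, speed-curvature
    correlation, number of speed peaks), catch-trial estimation of endpoint
    stiffness and the proportion of active force compensation, and exponential
    learning-curve fitting. Results are returned as tibbles with tidy()
    and glance() methods and ggplot2 autoplot() visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
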