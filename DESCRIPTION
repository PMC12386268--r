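Package: halfield
Title: Half-Field Irradiation Cell Migration Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for half-field irradiation
    time-lapse migration experiments. Generates synthetic single-cell
    trajectories (and label-image movies) with calibrated per-cell speed
    heterogeneity, classifies cells into in-field, out-of-field and
    exclusion regions of a half-shielded culture dish, recovers tracks by
    centroid detection and greedy nearest-neighbour linking, computes
    per-cell migration metrics (velocity, total path length, net
    displacement) and ensemble mean squared displacement with a linearity
    fit, and compares treatment groups against a shared control with
    Steel's many-to-one rank test plus a chi-square test on FUCCI
    cell-cycle state distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
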