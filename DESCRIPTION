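Package: cortsim
Title: Simulation of Acute Glucocorticoid Stress-Response Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating acute glucocorticoid (stress-hormone)
    response curves as function-valued traits. Individuals are drawn from a
    multivariate normal population over seven curve parameters (baseline,
    onset delay, time to maximum, maximum value, plateau duration, return
    duration, and recovery level), expressed repeatedly with controllable
    within-individual fidelity, realized as smoothed minute-resolution
    curves, and observed under realistic sampling designs with assay error.
    Includes repeatability statistics (per-timepoint intraclass
    correlations, profile repeatability, and area-under-the-curve
    repeatability in ground and increase modes), a fitness generator with
    configurable variance shares, and seeded scenario pipelines for
    evaluating how sampling designs and patterns of between- and
    within-individual variation affect what single-timepoint hormone
    measures can detect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    mgcv,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    patchwork,
    optparse,
    withr
Config/testthat/edition: 3
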