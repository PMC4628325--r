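Package: volresp
Title: Measurement-Variability-Based Response Thresholds for Tumour Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision thresholds for relative change of tumour volume on CT,
    derived from the measurement variability of the volumetric biomarker via
    the Geary-Hinkley transformation of a ratio of two approximately normal
    measurements. Provides closed-form confidence intervals for volume
    ratios, symmetric partial-response / progressive-disease thresholds,
    p-values and statistical power for the no-change test, a Monte Carlo
    engine validating the thresholds under normal, lognormal and uniform
    error models, volume-to-effective-diameter threshold extrapolation, a
    longitudinal multi-reader response-classification pipeline with
    baseline- and nadir-referenced assessments, a reader-agreement check
    against the model's predicted variability band, and a synthetic-cohort
    generator emulating a multi-reader NSCLC follow-up study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
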