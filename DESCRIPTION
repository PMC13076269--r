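Package: pde4vig
Title: Pharmacovigilance Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for disproportionality analysis of spontaneous
    adverse event reports in the FAERS quarterly ASCII format: case
    deduplication, primary-suspect cohort construction, four-algorithm signal
    detection (reporting odds ratio, proportional reporting ratio, Bayesian
    confidence propagation neural network information component, and the
    multi-item gamma-Poisson shrinker), sex-differential risk testing with
    false discovery rate control, system-organ-class aggregation by unique
    case, and time-to-onset analysis. Includes a synthetic report generator
    with planted signals and closed-form ground truth for end-to-end
    validation, plus volcano, forest, heatmap and onset-time figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
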