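Package: aeroeval
Title: Evaluation of Automatic Real-Time Pollen Monitors Against
    Hirst-Type Reference Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating automatic, image-recognition based
    pollen monitors (such as the BAA500) against the conventional
    Hirst-type volumetric trap. Implements reliability and data-gap
    statistics, manual-versus-automatic confusion matrices with
    per-class sensitivity and positive predictive value, main pollen
    season extraction by the 95% cumulative-percentage method
    (including the Annual Pollen Integral and peak traits), and
    paired-device comparability via correlation, ordinary
    least-squares trait regressions and median phenological offsets.
    A synthetic dual-device simulator generates seasonal
    concentration curves, Poisson counting noise, taxon-specific
    misclassification and two-level data gaps, so the whole pipeline
    runs reproducibly with inputs of known truth.
License: MIT
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
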