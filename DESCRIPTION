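Package: cgmboost
Title: Glycemic-Variability Features and AdaBoost Classification of Diabetes Type from CGM Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes 17 glycemic-variability features (daily and meal-window
    means, SDBG, LAGE, MODD, excess AUC, MAGE, excursion counts and
    time-in-range percentages) from continuous glucose monitoring day-curves
    at a configurable upper glucose threshold, and classifies type 1 versus
    type 2 diabetes with from-scratch discrete, Real, Gentle and Modest
    AdaBoost ensembles over decision stumps. Includes hold-out and stratified
    k-fold evaluation (accuracy, Matthews correlation coefficient),
    an upper-threshold sweep with per-iteration error curves, and a
    seeded simulator of labeled CGM cohorts for end-to-end testing.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
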