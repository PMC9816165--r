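Package: painerd
Title: Externally Validated Classification of Pain Intensity from EEG Band-Power Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-trial classification of low versus high pain
    intensity from peri-stimulus EEG. Implements a complete, reproducible
    pipeline: a synthetic-EEG generator with known ground-truth band-power
    modulations emulating a two-study pressure-pain paradigm; zero-phase
    temporal filtering and resampling; sliding-window multitaper power
    spectral density and its transformation to event-related
    desynchronisation (ERD) percentages collapsed over canonical frequency
    bands; a 15-statistic candidate feature grid with robust outlier
    interpolation and min-max scaling; univariate feature ranking with
    sequential selection; seven classifier families with grid-searched
    hyperparameters; and stratified cross-validation plus two-stage external
    validation with discrimination and calibration reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    ranger,
    e1071,
    glmnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
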