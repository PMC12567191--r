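Package: tgmo
Title: Therapeutically Guided Multidrug Combination Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An implementation of therapeutically guided multidrug
    optimization (TGMO) for cell-based combination screens. The package
    covers the full pipeline: normalization of viability readouts to the
    vehicle control, variable-slope dose-response fitting with IC20
    extraction and clinically-used-dose capping, construction and
    validation of orthogonal array composite designs (OACD), second-order
    stepwise response-surface regression on efficacy and
    therapeutic-window endpoints with Cook's-distance outlier handling,
    drug-drug interaction classification, iterative drug elimination, and
    selection of optimized drug combinations (ODC). A Bliss-independence
    screen simulator with planted pairwise interactions provides ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
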