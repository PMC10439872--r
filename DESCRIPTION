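Package: pacsel
Title: Treatment Selection Modelling for Primary Angle Closure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "pacsel@example.org",
           role = c("aut", "cre"))
Description: Models the hypotensive effect of the two first-line treatments
    for primary angle closure -- lens extraction (LE) and laser peripheral
    iridotomy (LPI) -- from pre-treatment clinical and anterior-segment
    biometry. Provides a calibrated synthetic cohort generator, a
    data-driven SIMCA one-class classifier for group-similarity testing and
    outlier screening, principal component regression of the IOP reduction
    with Procrustes cross-validation, counterfactual cross-arm prediction,
    and derivation of full (37-parameter) and short (4-parameter)
    treatment-selection indicators with a gray-zone recommendation rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
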