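Package: phenotherm
Title: Temperature-Dependent Development Models and Voltinism Projection
    for Egg Parasitoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits twelve temperature-dependent development-rate models
    (linear, Briere, Lactin, Logan, Kontodimas, Shi, Taylor, beta-type and
    beta families) to constant-temperature development data of egg
    parasitoids, selects the best model by fit statistics (S, AIC, BIC)
    combined with the biological plausibility of the estimated thermal
    thresholds, and projects annual voltinism and threshold-exceedance
    days from daily minimum/maximum temperature series under delta-change
    warming scenarios. Ships the published development data and fitted
    parameter sets for Telenomus remus and Trichogramma foersteri, and
    synthetic generators for development datasets and daily climate grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
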