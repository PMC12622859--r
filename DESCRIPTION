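Package: avtk
Title: Analytical Validation Toolkit for Sensor-Derived Digital Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analytical validation (AV) studies that compare a
    sensor-derived digital measure (DM), summarised per day, against
    clinical outcome assessment (COA) reference measures (RM) with daily
    or multiday recall periods. Implements recall-period temporal
    alignment of daily DM data to RM administration instances, 0-100
    rescaling of Likert-item totals, an agreement battery (Pearson
    correlation, simple and multiple linear regression with adjusted
    R-squared, and two-factor correlated-factor confirmatory factor
    analysis fitted by maximum likelihood with CFI, TLI, RMSEA and SRMR
    fit evaluation), and a synthetic AV-study simulator with known latent
    structure for validating the estimators by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    lava
Config/testthat/edition: 3
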