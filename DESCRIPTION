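Package: auditkrige
Title: Regression Kriging of Binary Virtual Neighborhood Audit Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spatial analysis of binary drop-and-spin virtual neighborhood
    audit items: logistic detrending on centered cubic spatial polynomials
    with optional rater adjustment, empirical and directional semivariography
    of deviance residuals, weighted-least-squares fitting of nested
    theoretical semivariogram models, local ordinary Kriging of residuals,
    back-transformed probability prediction, and cross-validated evaluation
    by RMSPE and ROC AUC. Includes a synthetic audit-data generator
    (hard-core location sampling, Gaussian random fields, rater effects,
    block-group layers) so that every stage is testable without access to
    the original audit data, plus transcribed summary tables from a
    county-wide 31-item audit for reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
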