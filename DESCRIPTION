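Package: pronioptim
Title: Response-Surface Optimization and Delivery Statistics for
    Finasteride-Loaded Proniosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computational pipeline behind a central-composite-design (CCD)
    formulation-optimization study of finasteride-loaded proniosomes:
    rotatable CCD construction with coded/actual unit conversion,
    full-quadratic response-surface regression with the Design-Expert style
    diagnostic suite (R-squared, adjusted and predicted R-squared, PRESS,
    adequate precision), Derringer desirability multi-response optimization,
    drug-release kinetic model fitting (zero-order, first-order,
    Korsmeyer-Peppas, Higuchi), Franz-cell cumulative permeation with
    withdrawal-replacement correction, transfollicular cumulation,
    entrapment-efficiency and drug-loading formulas, and Draize primary
    irritation index scoring.  Ships verbatim fixtures of the source study's
    printed design matrix and irritation scores plus synthetic-data
    generators so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
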