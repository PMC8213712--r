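Package: lulcsim
Title: Scenario Simulation of Land-Use/Land-Cover Change with Logistic
    Suitability, Markov Demand and CLUE-S Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for scenario simulation of land-use/land-cover (LULC)
    change in a subsiding coal-mining landscape: a lightweight categorical
    raster model with ESRI ASCII grid I/O, majority/mean resampling,
    Euclidean accessibility-distance and Horn slope derivation; per-class
    binary logistic suitability models with collinearity diagnostics and
    ROC evaluation; Markov transition-matrix estimation, annualization and
    class-area demand projection under policy scenarios; a CLUE-S-style
    iterative spatial allocator driven by conversion elasticities and an
    allowed-conversion matrix; kappa-based map-agreement validation; and a
    seeded synthetic landscape generator with known logistic and Markov
    structure so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    knitr,
    rmarkdown
Config/testthat/edition: 3
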