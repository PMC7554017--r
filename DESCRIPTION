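Package: luces
Title: Land-Cover Change Scenarios and Ecosystem-Service Trade-Off Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how land-cover change reshapes the supply of
    ecosystem services in urbanising regions. Provides a lightweight raster data
    model with ESRI ASCII grid input/output, a Markov-chain cellular-automata
    land-cover change model (transition-matrix estimation, logistic-regression
    transition potentials, neighbourhood-based spatial allocation, scenario
    rules for cropland protection and ecological restoration, kappa
    validation), six equation-based ecosystem-service valuation models (water
    yield, carbon storage, RUSLE soil conservation, NDVI-apportioned crop
    production, PM10 air purification, habitat quality), the trade-off/synergy
    degree (TSD) index with pairwise and spatial block variants, and a
    synthetic-landscape generator with known ground truth so every stage of the
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    stats,
    utils,
    EBImage,
    e1071,
    glmnet,
    pROC,
    yaml
Suggests:
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
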