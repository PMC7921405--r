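Package: fjordfe
Title: Benthic Iron Cycling Kinetics and Spatial Gradients in Glaciated Fjord Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies potentially bioavailable iron in fjord sediments from
    time-course extraction experiments. Fits a reactive continuum model of
    mineral dissolution kinetics to chemical (ascorbate) and microbial iron
    extraction curves with the extractable amount fixed from the observed
    plateau, and derives the pool's reducibility (apparent rate constant v/a),
    composition (heterogeneity index 1 + 1/v) and lability (initial dissolution
    rate). Also provides sequential-HCl iron speciation accounting, sulfate
    reduction rates from 35S radiotracer incubations with depth integration,
    log-linear (exponential) regression of surface iron pools along fjord
    transects, and a seeded synthetic-data generator that emulates the full
    sampling design so every stage of the pipeline can be validated against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    minpack.lm,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
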