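Package: rsga
Title: Dual-Reporter Synthetic Genetic Array Screen Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for dual-reporter synthetic genetic array
    (R-SGA) fluorescence screens in yeast deletion collections. Reads
    colony-array fluorescence and colony-size tables, removes border strains
    and size outliers, aggregates quadruplicate colonies, removes within-plate
    spatial artifacts from log2(GFP/RFP) ratios by per-plate LOESS, calls
    reporter-specific hits by Z-score against a matched control screen, and
    supports downstream flow-cytometry fold-change validation and
    hypergeometric term enrichment. Includes seeded simulators for colony
    arrays and flow-cytometry event data so every stage can be exercised and
    power-tested without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
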