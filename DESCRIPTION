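Package: melanospace
Title: Colour Spaces for Discrete Melanic Patterns and Their Congruence
    with Genetic, Geographic and Climatic Structure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing geographic variation of discrete melanic
    colour patterns in insects. Ordered colour modalities of body parts are
    fuzzy-coded into paired light/dark variables and ordinated by
    correspondence analysis into a "colour space"; morph separation is
    assessed by leave-one-out canonical variate cross-validation, and
    phenotypic integration and modularity are quantified from correlations
    of character vectors. Companion functions compute shared-allele
    microsatellite distances, pairwise haplotype distances, neighbor-joining
    trees, great-circle geographic distances and climate-PCA distances, and
    test congruence between the resulting structures with RV coefficients on
    principal coordinates (with Lingoes correction), population-level
    aggregation, RV-dissimilarity trees and per-individual distance-profile
    correlation heatmaps. A seeded synthetic-study generator produces full
    multi-layer datasets with known scenario parameters for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
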