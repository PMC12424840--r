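Package: phytomine
Title: Association Mining and Druggability Triage for Traditional-Medicine Pharmacopeias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mining cross-cultural pharmacopeia tables that link
    traditional-medicine formulas to plant species, phytochemicals, and
    free-text therapeutic indications. Implements a wildcard indication-term
    dictionary for four neuro-related disorder categories (anxiety/mood,
    movement/seizure, pain, sleep), per-compound indication-association
    percentages and the derived compound index, a sum-of-percentages
    candidate filter, species-indication linkage counts for chord-diagram
    export, multi-source composite metabolome ("meta-metabolome") assembly
    with eight-class phytochemical tallies, bipartite species-compound
    networks with Jaccard species projections, and druggability triage:
    molecular descriptors, 2048-bit circular fingerprints, Lipinski
    rule-of-five violation counts, weighted QED, and random-forest
    imputation of natural-product-likeness scores. A seeded synthetic-data
    generator provides datasets with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    igraph,
    ranger,
    generics,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
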