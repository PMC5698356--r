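Package: SporeSwitch
Title: Life-History Timing, Serial-Transfer Evolution and GO-Grouped
    Expression Analysis for Fungal Dispersal
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the trade-off between hyphal growth and conidia
    production in filamentous fungi under daily serial-transfer selection.
    Provides the closed-form optimal conidiation onset time together with a
    brute-force oracle, a stochastic serial-dilution simulator with mutable
    life-history traits and extinction accounting, a gene-ontology-grouped
    ANOVA pipeline for FPKM expression tables (fold-change filtering,
    log-share normalization, global cell-mean fit, per-term directional and
    temporal tests, deviation profiles), and synthetic-data generators with
    planted effects so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, GeneExpression, DifferentialExpression, Transcriptomics
RoxygenNote: 7.3.3
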