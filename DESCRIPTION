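Package: ionqtl
Title: Multi-Environment QTL Mapping and QTL-by-Environment Interaction
    Analysis for Seed Ionomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.invalid")
Description: Tools for dissecting genotype-by-environment control of seed
    elemental traits (the ionome) in recombinant inbred line (RIL)
    populations grown in unbalanced multi-environment designs.  Provides
    single-seed trait normalization (grouped MAD outlier flagging and
    residual-based seed-weight/run correction), broad-sense heritability
    from unbalanced two-way ANOVA, marker-regression LOD genome scans with
    permutation thresholds, penalized stepwise multi-QTL model selection
    with position refinement and cross-environment QTL merging, and two
    QTL-by-environment interaction tests: a location-covariate full-vs-
    additive model comparison with a three-step permutation null, and
    stepwise mapping on within-location between-year trait differences.
    Includes a synthetic-data generator that emulates the statistical
    structure of such studies so the whole pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
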