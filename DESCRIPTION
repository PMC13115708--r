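Package: snvburden
Title: Cumulative Gene-Level Burden Scoring of Somatic SNVs Across
    Functional-Effect Analyzers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Aggregates somatic single-nucleotide variants from paired
    tumor/normal VCF cohorts into per-gene burden scores. Scores from
    functional-effect analyzers (SIFT, PolyPhen, CADD, FATHMM-XF) are
    harmonized to a common direction, anchored min-max normalized at each
    analyzer's deleteriousness cutoff, and combined into a cumulative
    gene score: a transcript-length-penalized, tumor-minus-normal
    frequency-weighted sum, averaged over a gene's transcripts. An
    integrative variant score averages all available analyzers. Gene
    rankings are evaluated with a standardized average rank (SAR)
    statistic against a random-gene-set resampling null. A synthetic
    somatic-cohort simulator with a ground-truth manifest makes the whole
    pipeline testable end to end without external data.
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
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
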