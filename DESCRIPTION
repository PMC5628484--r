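Package: knocknet
Title: Knockdown Transcriptomics Screening, Directional Enrichment and
    Interaction-Network Hub Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for two-group (negative control versus
    shRNA knockdown) expression profiling experiments: RMA-style
    preprocessing (intensity floor, quantile normalization, log2,
    median-polish probe-set summarization), differential-expression
    screening by fold change and Benjamini-Hochberg corrected p,
    directional gene-set enrichment with two-sided Fisher's exact and
    chi-square tests, pathway-pathway and gene-gene interaction network
    construction from KGML-subset relation documents with degree-based
    hub ranking, and qPCR validation math (2^-ddCt relative
    quantification, RNA quality gating, array/qPCR concordance). A
    synthetic-data generator with known ground truth drives recovery and
    calibration tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    yaml,
    optparse
Config/testthat/edition: 3
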