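Package: sipact
Title: Stable Isotope Probing Gradient Analysis and Taxon Activity Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis of DNA stable isotope probing (DNA-SIP) experiments
    read out by amplicon sequencing. Provides percent-of-gradient
    normalization of CsCl gradient fractions, density-window pooling, a
    per-taxon activity statistic (enrichment of relative abundance in
    dense pooled fractions of the labeled gradient) with Fisher exact
    tests and Benjamini-Hochberg false discovery rate control,
    copy-number-normalized KEGG-ortholog profile prediction and
    enrichment, isotope-ratio mass spectrometry delta-notation
    calibration with two-point normalization and Mann-Whitney group
    comparison, and a synthetic-data generator that emulates isopycnic
    centrifugation of partially isotope-labeled bacterial DNA with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
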