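Package: phosphosig
Title: Phospho-Anchored Transcriptional Signatures from Paired Expression and RPPA Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives and scores transcriptional gene-expression signatures
    anchored to reverse-phase protein array (RPPA) phospho-protein
    measurements. Provides sum-based RPPA pathway activity scores for the
    PI3K/AKT and mTOR pathways, phospho-high versus phospho-low
    differential expression with an mRNA-phosphoprotein correlation
    filter, a per-sample ratio-of-means signature score (mean of
    up-regulated over mean of down-regulated genes, z-scaled within each
    cohort), and nonparametric comparison of scores across body-mass-index
    and menopause strata. A paired expression/RPPA/clinical cohort
    simulator with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
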