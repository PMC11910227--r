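Package: epireprog
Title: Paired Tumor Methylome and Transcriptome Biomarkers of Epigenetic
    Immune Reprogramming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Correlative multi-omic biomarker analysis for paired
    baseline/on-treatment tumor biopsies under low-dose hypomethylating
    therapy. Implements probe-level quality control and paired differential
    methylation on EPIC-style beta matrices (moderated and ordinary paired
    tests on M values, sign-flip differentially methylated regions,
    promoter deltas and Stouffer-combined gene-level Z statistics),
    RPKM normalization and geometric-mean immune signature scoring
    (IFN-gamma, STING, M1/M2), reference-based methylome cell-type
    deconvolution, directional logistic gene-set enrichment, and
    trial-style molecular endpoints (molecular-responder and
    biologically-effective-dose classification, tumor-suppressor-gene
    hypomethylation reversal, neutrophil-to-lymphocyte ratio, H-scores,
    exact rank-sum tests, Kaplan-Meier summaries). A fully specified
    synthetic paired-biopsy cohort generator with planted responder
    effects makes every stage testable without access to patient data.
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
    generics,
    jsonlite,
    fgsea,
    limma,
    e1071,
    quadprog,
    survival,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
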