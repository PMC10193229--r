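Package: uevstress
Title: Urinary Extracellular-Vesicle Transcriptomics and the Kidney Stress
    Score in Diabetic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for urinary extracellular-vesicle (uEV) mRNA
    sequencing in diabetic kidney disease: sample quality control by
    intergenic-read fraction and RNA-degradation flags, robust-transcriptome
    derivation, TMM/CPM normalization, rank-based inverse-normal
    transformation, covariate-adjusted negative-binomial GLM differential
    expression with Bonferroni control, kidney tissue-similarity mapping
    against enriched/depleted gene sets, a six-gene transcriptional stress
    score, and its association with long-term eGFR decline (CKD-EPI
    creatinine equation, annual means, per-group slopes, CKD staging, ROC,
    adjusted regression). Includes a synthetic-cohort generator with planted
    effects so every stage is testable without access to patient-level data.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
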