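Package: screverse
Title: Treatment-Reversal Analysis of Kidney Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for asking whether a treatment pushes a diseased
    transcriptome back toward the healthy state, at single-cell resolution
    and per nephron segment. Provides 10x triplet / CSV / GMT readers, a
    negative-binomial cohort simulator with planted reversal structure,
    cell-level quality control and marker-based segment annotation,
    pseudobulk moderated-t differential expression with empirical-Bayes
    variance shrinkage, classification of transcripts as suppressed or
    enhanced by treatment from two contrasts, directional Fisher
    over-representation analysis, and single-sample gene-set (ssGSEA)
    pathway scoring with group-delta summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
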