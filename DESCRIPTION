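Package: drlink
Title: Differentially Regulated Links Between Two Disease Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for two-disease transcriptomic crosstalk analysis:
    probe collapsing and multi-cohort merging, empirical-Bayes batch correction,
    moderated-t differential expression with per-disease thresholds, crosstalk
    gene intersection with hypergeometric gene-set enrichment, a
    differentially-regulated-link (DRL) statistic contrasting per-group
    regression slopes between case and control samples, protein-protein
    interaction bridge networks with topology metrics, and lasso/ROC screening
    of a candidate gene panel. Ships a fully synthetic data generator with a
    truth ledger so every stage is testable without external downloads.
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
    glmnet,
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    sva,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
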