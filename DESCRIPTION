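Package: methylaml
Title: DNA Methylation Subtype Classification and Outcome Analysis for
    Pediatric AML
Version: 0.1.0
Authors@R:
    person("methylaml", "authors", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing Illumina 450k-style beta-value matrices in
    pediatric acute myeloid leukemia: detection p-value masking and probe
    filtering, MDS-based outlier flagging, dual unsupervised CpG feature
    selection (PCA loadings and a low-variance/high-correlation filter),
    nested cross-validated one-vs-rest cytogenetic subtype classification
    with permutation validation, one-vs-rest differential methylation with
    Benjamini-Hochberg correction, intra-subtype heterogeneity clustering,
    and within-subtype methylation-group survival analysis (Kaplan-Meier,
    log-rank, Cox proportional hazards). Includes a synthetic-cohort
    generator that emulates the statistical structure of a 450k AML cohort
    so the whole pipeline is testable without restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    FNN,
    glmnet,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    withr,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
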