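Package: prspipe
Title: Polygenic Risk Score Construction and Evaluation for Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for case-control polygenic risk score (PRS)
    analysis of candidate SNP panels: genotype and sample quality control
    (call rate, Hardy-Weinberg equilibrium in controls, minor allele
    frequency), per-SNP additive logistic association with optional age
    adjustment, linkage-disequilibrium r-squared pruning, PRS construction
    under three model-selection rules, and evaluation by quartile odds
    ratios, continuous trend odds ratios and ROC AUC. Includes a two-cohort
    synthetic case-control simulator with LD blocks and a configurable
    disease model so every stage is testable without access to private
    genotype data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    pROC,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
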