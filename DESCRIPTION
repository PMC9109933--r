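Package: mrorient
Title: SNP Orientation Sensitivity of MR-Egger Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the allele coding (orientation) of SNPs
    affects Mendelian randomization estimators based on two-sample GWAS
    summary statistics. Provides a simulator for individual-level data under
    a structural causal model with horizontal pleiotropy and its reduction to
    per-SNP summary statistics, from-scratch inverse-variance weighted (IVW),
    MR-Egger and Radial-Egger estimators, coding-scheme machinery (default
    exposure-increasing, oracle, random and exhaustively enumerated codings),
    InSIDE and NOME (I-squared) diagnostics, and drivers that run
    coding-sensitivity scans and replication studies of estimator bias under
    re-orientation of SNPs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
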