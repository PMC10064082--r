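Package: mrgap
Title: Two-Sample Mendelian Randomization and Glycation-Gap Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics and for observational glycation-gap analysis.
    Implements instrument selection at genome-wide significance, LD-proxy
    substitution, allele harmonization with palindromic-SNP handling, and the
    standard univariable MR estimators (inverse-variance weighted, MR-Egger,
    weighted median, simple and weighted mode) with Cochran's Q
    heterogeneity, I-squared, instrument F-statistics and leave-one-out
    sensitivity analysis. Inverse-variance weighted multivariable MR with
    conditional instrument-strength diagnostics estimates direct effects of
    one exposure adjusted for others. A companion observational pipeline
    computes the triglyceride-glucose index, predicted HbA1c from fasting
    glucose, the glycation gap, stratified gap regressions, regression
    diagnostics and 0.632-bootstrap optimism validation. Seeded synthetic
    generators for GWAS summary statistics and patient-level cohorts make
    every stage testable without access to consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
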