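Package: mrmediate
Title: Two-Sample and Two-Step Mediation Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) with GWAS
    summary statistics: reading, validation and allele harmonization of
    summary-statistics tables; instrument selection by association
    threshold, greedy LD clumping and F-statistic screening; closed-form
    inverse-variance-weighted (IVW) and MR-Egger estimators with Cochran's
    Q heterogeneity statistics; an MR-PRESSO style resampling test for
    pleiotropic outlier instruments (global, per-SNP outlier and
    distortion components); two-step mediation MR with delta-method
    confidence intervals for the mediation proportion; a multi-candidate
    mediator screen; and a synthetic GWAS summary-statistics generator
    that simulates an exposure-mediator-outcome causal chain with
    configurable pleiotropy, LD blocks and allele-coding noise for
    benchmarking every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
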