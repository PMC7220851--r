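Package: ampdriver
Title: Amplification-Dependent Driver Gene Discovery from Somatic
    Copy-Number and Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative pipeline for discovering candidate cancer driver
    genes whose expression depends on recurrent somatic copy-number gain.
    Implements multi-scale recurrent copy-number region calling with a
    cyclic-shift permutation false-discovery-rate estimator, copy-number
    to expression Spearman correlation filtering under Benjamini-Hochberg
    control, siRNA proliferation-screen hit calling with deconvolution
    validation, negative-binomial Wald differential expression for
    knockdown experiments, and Kaplan-Meier / proportional-hazards
    survival relevance scoring, together with a synthetic-data generator
    that emulates the statistical structure of tumor-cohort inputs so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
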