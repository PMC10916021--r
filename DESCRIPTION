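Package: gbdmr
Title: Differentially Methylated Region Detection via Generalized Beta Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differentially methylated CpG regions (DMRs) from
    Illumina-style beta-value matrices. CpG sites are ordered genomically and
    chained into blocks wherever adjacent Pearson correlation exceeds a
    threshold; each block is modelled jointly with a multivariate generalized
    beta (Libby-Novick) regression with a logit link between the phenotype and
    the per-CpG mean methylation, and the phenotype effect is tested with a
    likelihood-ratio test on one degree of freedom. Includes simplified
    comparison methods (per-CpG linear-model EWAS on M-values and an
    inverse-variance-weighted region statistic), a Monte-Carlo simulation
    harness generating correlated beta-distributed methylation data through a
    Gaussian copula, and the closed-form power of the inverse-variance-weighted
    statistic under compound-symmetric correlation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    parallel,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
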