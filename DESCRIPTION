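Package: gxevc
Title: Scalable Exact Set-Based Gene-Environment Interaction Variance-Component Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Set-based variance-component score tests for gene-environment
    interaction (GxE) on continuous traits, scaled to biobank-size samples.
    The test statistic and its weighted chi-square null distribution are
    computed exactly, never forming any n x n matrix: the inverse of the
    phenotypic covariance V = tau*G*G' + sigma*I is applied through a
    Sherman-Morrison-Woodbury operator with a cached L x L Cholesky factor,
    the nuisance variance components (tau, sigma) are estimated by a
    restricted maximum likelihood EM algorithm run in the QR-projected
    (n - P)-dimensional space, and the null eigenvalue spectrum is obtained
    from an L x L reduction of the n x n kernel matrix. A dense reference
    implementation, tail probabilities for weighted chi-square mixtures
    (characteristic-function inversion, moment matching, and Monte Carlo),
    rare-variant genotype simulators, and a reproducible simulation-study
    harness are included, together with readers for PLINK additive-coded
    text genotypes and gene-range scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
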