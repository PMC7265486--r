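Package: synstrat
Title: Drug Synergy Prioritization and Stratification from Monotherapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate drug combinations and stratifies cancer
    cell lines for synergistic response using only monotherapy drug response
    (IC50), basal gene expression and nominal drug-target annotation.
    Pathway activities are scored from expression with perturbation-derived
    gene weights (PROGENy-style footprint signatures); a Bayesian matrix
    factorization with side information (Macau-style Gibbs sampler) links
    drug targets to pathway activities through an interaction matrix; the
    Pearson correlation of two targets' interaction profiles defines their
    functional similarity, which ranks combinations; Delta Pathway Activity
    models predict per-cell-line synergy for known-synergistic target
    pairs. Includes permutation significance (empirical two-tailed p,
    count-ratio Bayes factors, FDR flags), a Loewe-additivity excess-volume
    synergy scorer for dose-response matrices, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
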