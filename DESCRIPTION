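Package: twostepQSAR
Title: Two-Step L1/L2 Regularized Linear QSAR Models for Fixed-Length Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds linear binding-affinity (pIC50) regression models for
    fixed-length peptides in the small-n / large-d regime. Peptides are
    encoded by concatenating physico-chemical descriptors, one-hot (sparse)
    encoding and BLOSUM62 rows; features are normalized with training-set
    statistics. Model fitting follows a two-step procedure: an
    L1-regularized fit with a robust logarithmic loss, minimized by the
    resilient-propagation (Rprop) optimizer, selects features whose weights
    stay above a small threshold; an L2-regularized refit on the survivors
    yields the deployable model. Both regularization strengths are chosen
    by repeated k-times n-fold cross validation. Includes a closed-form
    ridge solver, q-squared and Spearman rank correlation metrics, a
    synthetic-data simulator for the peptide QSAR regime, plotting and
    broom-style tidiers, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Biostrings,
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
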