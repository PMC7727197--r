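Package: censelect
Title: Benchmarking Variable-Selection Methods for Highly Collinear
    Social-Environmental Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based benchmarking of variable-selection strategies for
    high-dimensional, highly collinear covariate tables such as census-derived
    neighborhood measures. Provides a Gaussian-copula synthetic data generator
    with zero-inflated and log-normal marginals and block collinearity,
    power-calibrated effect sizes, Spearman-distance complete-linkage variable
    clustering (threshold and bootstrap-stability variants), univariable
    Bonferroni screening, cross-validated lasso and elastic net, a native
    sparse group lasso solver, random-forest and bagging selection via
    variable-importance confidence intervals, a compact Bayesian additive
    regression trees sampler with permutation-based inclusion-proportion
    thresholds, and a discovery/validation evaluation pipeline with strict and
    surrogate-aware scoring and F2 summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    ranger,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
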