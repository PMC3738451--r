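Package: mtbvs
Title: Multi-Trait Bayesian Variable Selection by Evolutionary Stochastic Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sparse Bayesian variable selection for genome-wide association
    studies of one or more correlated quantitative traits. Implements a
    parallel-tempered evolutionary stochastic search sampler over multi-SNP
    regression models with a conjugate multi-response Zellner-Siow g-prior
    marginal likelihood, a beta-binomial sparsity prior on model size
    parameterized by its prior mean and standard deviation, permutation-based
    empirical false discovery rate calibration of marginal posterior inclusion
    probabilities, and the Ratio of Bayes Factors statistic for ranking the
    strength of association of a variant across groups of phenotypes. Includes
    genotype quality control, greedy r-squared tagging, inverse-normal trait
    transformation, covariate adjustment by projection, a matrix-variate
    phenotype simulator with variance-explained calibration for power studies,
    and ROC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
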