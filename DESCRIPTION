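Package: hybridgs
Title: Genomic Selection for Hybrid Rice from an NC II Training Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome prediction of hybrid performance from inbred
    parental genotypes, built around a North Carolina II factorial training
    design (female lines crossed to male-sterile testers). Implements six
    prediction methods under one fit/predict contract: GBLUP with a
    marker-product kinship and a profiled-REML variance ratio estimated by
    safeguarded Newton iteration, coordinate-descent LASSO, BayesB with a
    mixture prior sampled by a collapsed Gibbs chain, PLS1, Gaussian-kernel
    support vector regression, and multi-kernel RKHS regression. Provides
    replicated cross-validation predictability, trait-by-method ANOVA with
    Tukey letter groups, marker-density and training-size subsampling
    experiments, broad-sense heritability from balanced multi-environment
    trials, exhaustive prediction and ranking of untested crosses with
    top-k gain, and a synthetic-data generator that emulates the NC II
    study design at target heritabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    e1071,
    withr
Config/testthat/edition: 3
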