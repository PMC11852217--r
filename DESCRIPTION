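Package: pigGP
Title: Genomic Prediction of Pig Reproduction Traits with Weighted Kinship and Machine Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genomic prediction of lowly heritable
    reproduction traits in small pig populations. Provides seeded simulation of
    block-LD genotypes and additive trait architectures, fixed-effect phenotype
    correction and residual standardization, chip-style SNP quality control with
    removal bookkeeping and an imputation-concordance metric, single-SNP GWAS
    with Tracy-Widom selected principal-component covariates, GWAS-ranked nested
    SNP density panels, plain and prior-information-weighted VanRaden genomic
    relationship matrices, AI-REML heritability estimation, GBLUP and the
    Bayesian alphabet (Bayes A, B, C, Bayesian LASSO, Bayesian ridge) as Gibbs
    samplers, five machine-learning regressors on kinship features (kernel ridge
    regression, CART, random forest, gradient boosting with gradient-based
    one-side sampling, AdaBoost.R2), and an evaluation harness with fivefold
    cross-validation, Gaussian-process Bayesian hyperparameter optimization,
    independent testing, and one-way ANOVA utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
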