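Package: cqbatch
Title: Batch Effect Correction for Microbiome Count Tables via
    Conditional Quantile Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Removes batch effects from zero-inflated microbiome taxa read
    count tables while preserving the effects of key variables of interest.
    Each taxon is modelled with a two-part conditional model: logistic
    regression for presence-absence and linear quantile regression on
    jittered positive counts over a grid of quantile levels. Per-sample
    original and batch-free conditional quantile functions are assembled
    and every observed count is transported to the value at the same
    percentile of the batch-free distribution, aligning all batches to a
    chosen reference batch. Includes penalized, composite and
    quantile-matching fitting strategies with a two-layer tuning procedure
    driven by PERMANOVA R2, a library-size preserving variant, a
    zero-inflated Dirichlet count simulator for operating-characteristic
    studies, and an evaluation battery (Bray-Curtis and Aitchison
    distances, PERMANOVA R2, per-taxon association testing with BH-FDR,
    cross-validated random-forest prediction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    parallel,
    randomForest,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
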