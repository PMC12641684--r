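Package: latentrad
Title: Handcrafted Radiomics Versus Latent Deep Features for Hemorrhagic
    Stroke Outcome Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline comparing handcrafted
    radiomics (shape, first-order, GLCM and GLRLM texture families, with
    Laplacian-of-Gaussian and wavelet variants) against latent deep features
    from a multiscale U-shaped segmentation encoder and a variational
    autoencoder with an optional adversarial term, for predicting poor
    3-month outcome and hematoma expansion after intracerebral hemorrhage.
    Includes a synthetic pseudo-CT phantom generator with planted shape and
    texture signal, non-negative matrix factorization feature reduction fit
    on training folds only, a leakage-guarded classifier grid over seven
    input configurations, six classifiers and four outcomes, and the
    accompanying comparison statistics (Friedman, exact Wilcoxon signed-rank,
    multiplicity corrections, DeLong AUC comparison, cohort-table tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    randomForest,
    ranger,
    xgboost,
    e1071,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
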