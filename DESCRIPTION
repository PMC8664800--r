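Package: facejudge
Title: Predicting and Auditing Human Social Judgments from Facial Feature Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling consensus human social judgments of faces
    (e.g. trustworthy, dominant, attractive on 1-7 Likert scales) from
    numeric facial feature spaces, and for auditing what such models
    actually learn. Implements per-attribute regularized linear regression
    (ridge, LASSO, OLS) with repeated random-split cross-validation for
    regularization selection, bootstrap accuracy estimation with
    identity-aware resampling for multi-image datasets, permutation-based
    chance thresholds with Benjamini-Hochberg false discovery rate
    correction, variance partitioning of out-of-sample explained variance
    between pairs of feature spaces, full cross-prediction specificity
    matrices, and semi-partial residual cross-prediction analysis.
    Includes a 68-point landmark facial-geometry feature extractor, PCA
    reduction of high-dimensional feature spaces with predictive component
    count selection, a seeded synthetic-data generator emulating the
    low-dimensional latent structure of social judgments, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
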