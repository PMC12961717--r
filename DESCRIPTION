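Package: franklinra
Title: Embedding-Based Risk Adjustment for Healthcare Cost Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for machine-learning risk adjustment of annual healthcare
    costs from age, sex, and diagnosis codes. Implements a cluster-similarity
    risk model: diagnosis-code embeddings learned from within-profile
    co-occurrence (positive pointwise mutual information plus truncated
    singular value decomposition), spherical k-means clusters over the
    embedding space, per-beneficiary maximum-similarity cluster features, and
    a gradient-boosted regression on log cost with decile predictive-ratio
    calibration. Ships a structurally faithful hierarchical condition category
    (HCC) style linear baseline, an actuarial evaluation suite (log-scale R2,
    Spearman rho, Kolmogorov-Smirnov distance, extreme-cost classification,
    percentile prediction-error frequencies, within-decile dispersion, and a
    predictive-ratio variance decomposition into structural and residual
    dispersion factors), a favorable-selection financial-impact simulator, and
    a synthetic claims generator so that every stage is testable without
    restricted claims data.
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
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
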