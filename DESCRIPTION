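Package: cpmetals
Title: Gestational Metal and Essential Element Mixtures and Cerebral Palsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and inference pipeline for nested case-control
    studies of gestational exposure to toxic metals and essential elements
    and cerebral palsy in children. Provides a calibrated synthetic cohort
    generator (Gaussian-copula log-normal exposures, analytical-round batch
    effects, below-LOD/LOQ censoring), QC-ratio batch normalization,
    winsorization, bounded multiple imputation with an EM multivariate
    normal model and Rubin's-rules pooling, elastic-net stability selection
    with permutation p-values and Benjamini-Hochberg assessment, pooled
    logistic effect estimation with natural-spline nonlinearity checks and
    interaction models, a sensitivity-analysis suite, and quantile
    g-computation of joint mixture effects with signed weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    splines,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
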