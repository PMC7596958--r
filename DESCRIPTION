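Package: esmdr
Title: Efficient Survival Multifactor Dimensionality Reduction for
    Epistasis Detection in Age-of-Onset GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects gene-gene interactions associated with censored
    age-of-onset outcomes by replacing event time and status with
    covariate-adjusted martingale residuals from a Cox null model and
    applying quantitative multifactor dimensionality reduction (MDR)
    risk classification with cross-validated exhaustive k-way search.
    Includes a log-rank-based survival MDR baseline, null and purely
    epistatic survival simulators with type-I error and power
    estimators, and a downstream prediction pipeline (LD pruning,
    lasso-penalized Cox selection, Kaplan-Meier risk stratification and
    time-dependent ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
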