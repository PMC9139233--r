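Package: flowMRD
Title: Automated Gating and Minimal Residual Disease Quantification for
    Chronic Lymphocytic Leukemia Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-level classification of 10-color chronic lymphocytic
    leukemia (CLL) minimal residual disease (MRD) flow cytometry data with a
    fully connected neural network, a hybrid full-cohort/low-count cascade
    for MRD status designation and quantification, a synthetic cytometry
    cohort generator with uncompensated spectral overlap and spike-in
    dilution series, and the method-comparison statistics used to validate
    automated gating against expert analysis (per-class diagnostic metrics,
    rank-based AUC, Clopper-Pearson intervals, Passing-Bablok regression).
    Includes a reader and writer for Flow Cytometry Standard (FCS) 3.0/3.1
    list-mode files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
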