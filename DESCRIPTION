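Package: netfingerprint
Title: Connectome-Based Predictive Modelling of Drinking Severity with
    Molecular Map Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Task-based functional connectomics pipeline linking brain
    connectivity to alcohol-use severity. Builds a principal-component
    severity index from a 15-measure drinking battery, computes
    condition-specific node-by-node connectivity matrices, runs
    connectome-based predictive modelling (covariate-adjusted edge
    selection, network strengths, leave-one-out or k-fold cross-validated
    prediction, permutation inference), summarises selected networks over
    canonical-network anatomy, and spatially correlates regional effect
    maps with receptor/transporter density maps. A synthetic-cohort
    generator with planted ground truth lets the whole chain run and be
    validated without restricted data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Matrix,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
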