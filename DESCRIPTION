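Package: ppcOutliers
Title: Posterior Predictive Outlier Detection for Negative Binomial RNA-seq Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quality control for differential-expression results by posterior
    predictive checks. Fits a joint hierarchical negative binomial regression
    across transcripts (transcript baselines with a mean-overdispersion trend,
    per-sample sequencing-depth exposures, user covariates), generates the
    theoretical count distribution for every biological-replicate/transcript
    pair, and runs a two-step discovery/test procedure - quarantine of
    deleterious outliers, truncated-likelihood refit, and one-sided tests at a
    false-positive-rate-allocated interval width - to flag observations that do
    not fit the model. Includes a synthetic-data generator and the calibration,
    truncation-bias and approximation-error experiments used to validate the
    procedure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
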