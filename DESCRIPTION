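Package: effconn
Title: Classification-Based Detection of Effective Connectivity Between Timeseries
Version: 0.1.0
Authors@R:
    person("effconn", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to benchmark effective-connectivity detection between
    multivariate neural timeseries. Provides two generative models with known
    ground-truth causal structure -- a biophysically plausible network of three
    interconnected leaky integrate-and-fire (LIF) circuits emitting local field
    potential (LFP) proxies, and a stationary multivariate autoregressive (MAR)
    signal/noise mixture -- together with a supervised causal-structure
    classifier over a Granger-style feature space, the conditional Geweke index
    baseline with chi-square p-values, cross-correlation and p-value
    diagnostics, pooled per-edge ROC/AUC evaluation with bootstrap confidence
    intervals, and a command-line pipeline for dataset generation,
    featurization and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
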