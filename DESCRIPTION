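Package: latentconn
Title: Joint Latent-Space Modelling of Brain Connectomes and Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a joint Bayesian generative model in which each subject's
    functional connectome is reduced to a one-dimensional latent position
    vector that is coupled, through a multivariate normal prior, to a latent
    behavioural score underlying a battery of neuropsychological indicators.
    Provides a blocked Gibbs sampler with convergence diagnostics,
    transductive prediction of held-out behaviour under repeated train/test
    splits, dummy-variable regression of prediction accuracy on fMRI
    condition, node-level brain-behaviour covariance biomarker detection
    with functional-system profiling, a connectome-based predictive
    modelling (CPM) and ridge baseline, and a synthetic-data generator that
    simulates connectomes and behaviour exactly under the generative model
    with planted biomarker nodes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    glmnet,
    MASS,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
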