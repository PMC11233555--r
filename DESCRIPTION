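Package: spikecoupling
Title: Poisson GAM Encoding Models and Coupling-Filter Analyses for Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits penalized Poisson generalized additive models to simultaneously
    recorded spike trains, with B-spline tuning functions for continuous task
    covariates, temporal filters for task events, spike history, and directed
    unit-to-unit coupling. Provides posterior-based confidence intervals,
    covariate-inclusion tests, and likelihood-based fit scores; analyses of
    coupling strength and cross-context stability with permutation-based chance
    and ceiling references; condition-averaged PCA of time-warped population
    trajectories with a d-prime permutation test; and within- and cross-context
    population decoding (lasso and a small feed-forward network) together with a
    tuning-preserving shuffle of noise correlations. Includes a synthetic
    closed-loop navigation-to-target session generator with known ground truth
    so every analysis stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    splines,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
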