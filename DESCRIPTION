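Package: lgpois
Title: Mode-Matched Log-Gaussian Approximation for Over-Dispersed Poisson
    Regression and Additive Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-form estimation for over-dispersed Poisson regression
    and Poisson additive mixed models via a mode-matched log-Gaussian
    working response. The transform log((y + 0.5)/z) - (1 + 0.5 r)/(y + 0.5),
    where r is the share of zero counts, blends a mode-based and a mean-based
    log-Gaussian approximation; a two-step plug-in estimator then recovers
    coefficients, their covariance, and the dispersion parameter without
    iterative likelihood maximisation, avoiding the identification problem
    that destabilises Poisson maximum likelihood for small samples with many
    zeros. Includes comparator estimators (Poisson/over-dispersed Poisson
    IRLS, log-linear and Taylor Gaussian approximations, negative binomial),
    low-rank Gaussian-process spatial and group random effects fitted by
    REML, seeded simulators for over-dispersed counts, and a Monte Carlo
    benchmarking harness reporting RMSE, bias, and standard-error
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
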