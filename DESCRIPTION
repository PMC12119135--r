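Package: microdyn
Title: Simulation, Imputation and Bayesian Inference of Microbial
    Community Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal microbial community data: forward
    simulation under vector-autoregressive (VAR), species-metabolite
    (MVAR), generalized Lotka-Volterra (gLV) and consumer-resource (CR)
    models; Gaussian-process regression for imputing missing time-series
    observations with uncertainty bands; inference of interaction
    matrices from time series by ordinary/ridge least squares and by
    Bayesian MCMC with normal, horseshoe and covariance priors; and
    eigenvalue-based stability analysis of inferred discrete-time
    interaction matrices across posterior samples. Includes a tidy-CSV
    time-series format, a YAML-configured impute-normalize-infer-stability
    pipeline, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    deSolve,
    jsonlite,
    rjags,
    stats,
    tools,
    utils,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
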