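Package: fhstable
Title: Robust Bayesian Small Area Estimation with Alpha-Stable Random Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Area-level small area estimation with heavy-tailed random effects.
    Extends the Fay-Herriot model by letting the area random effects follow a
    symmetric alpha-stable law, estimated by a bespoke MCMC sampler that
    combines Gibbs updates (regression coefficients, random effects, global
    scale), rejection sampling for the positive-stable local mixing variables,
    and a Metropolis-Hastings step for the tail index. Includes Gaussian and
    Student-t random-effect baselines, a four-scenario simulation-study
    generator, and evaluation tools (deviance measures, empirical coverage,
    DIC, leave-one-out cross-validation).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
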