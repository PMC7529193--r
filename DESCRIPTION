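Package: rvvm
Title: Estimation and Inference with Random-Variable-Valued Measurements
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for sample data subject to response process error, where
    each recorded observation is itself a finitely supported probability
    measure (a random-variable-valued measurement, RVVM) rather than a fixed
    number.  Provides measure-valued data containers with a plain-text CSV
    dialect, the Poisson-binomial success-count measure implied by
    heterogeneous Bernoulli measurements, closed-form conjugate Beta-mixture
    posteriors for a Bernoulli proportion with generalized Bayes estimates and
    posterior standard deviations, empirical calibration diagnostics against
    gold-standard truths, Bayesian linear and logistic regression via pooling
    of complete-data posteriors over measure completions, synthetic data
    generators for a bird-banding sex-assessment scenario and a clinical
    rating-scale scenario, and packaged simulation studies of estimator bias
    and consistency.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
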