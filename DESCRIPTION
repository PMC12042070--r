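Package: frpred
Title: Predict Predator Functional Response Parameters from Energetic
    Demand and Prey Density Extremes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an energetic-constraint ("two rules") theory of
    predator functional responses: a predator's feeding rate must meet its
    energetic demand at the low prey densities it is likely to experience,
    and its feeding rate should saturate near the highest prey densities it
    experiences.  From these two rules the Holling type II space clearance
    rate and handling time are predicted from predator energetic demand,
    prey energy density, prey mass, and the extremes of prey density.  The
    package provides the closed-form theory, Bayesian log-log mass-scaling
    regressions (Damuth-law density and Kleiber-law metabolic fits via
    JAGS) with posterior-predictive quantiles, model II (major axis and
    reduced major axis) regression with 95% confidence intervals,
    power-law exponent propagation for the predicted allometries of both
    parameters, a replication pipeline (exclusion filters, per-record
    prediction, observed-versus-predicted comparison, auxiliary analyses,
    field-study mode), and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
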