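Package: compgrowth
Title: Composite von Bertalanffy Growth Models for Human Height and Weight
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Causal parametric modelling of human height and weight growth as
    the sum of five gated Putter/von Bertalanffy-type component processes with
    power-law (allometric) coupling between body radius and height. Provides
    closed-form component and composite trajectories, velocities and
    asymptotes; preparation of longitudinal anthropometric records on a
    total-age-since-conception scale (conception anchoring, carry-forward
    densification); a synthetic-data generator emulating temporally dense and
    sparse measurement designs with lognormal measurement error; Bayesian
    multilevel estimation of all model parameters via a blocked
    Metropolis-within-Gibbs sampler with group-level and person-level random
    effects that covary across growth processes; posterior summaries including
    highest posterior density intervals, group contrasts, age-weighted
    allometric and metabolic parameter trajectories and trajectory
    descriptives; and counterfactual simulation of metabolic healthcare
    interventions. A command-line interface ties simulation, preparation,
    fitting, summarising and intervention into reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
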