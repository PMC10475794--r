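Package: wearssm
Title: Bayesian State-Space Modelling of Multimodal Wearable Biosensor Data
Version: 0.1.0
Authors@R:
    person("Multi-Sensor", "Modelling Team", email = "dev@wearssm.org",
           role = c("aut", "cre"))
Description: Personalized dynamical modelling of continuous glucose monitor
    (CGM), physical activity, heart rate (HR) and heart rate variability (HRV)
    recordings together with a timestamped meal log. Three nested
    continuous-time linear Gaussian state-space models are fitted per
    participant: a glucose model with meal impulse responses and a 24-h
    sinusoidal baseline; an activity-driven HR/HRV model with correlated
    fluctuations; and a combined five-dimensional model coupling the physical
    and heart activity signals to glucose. Exact stochastic differential
    equation discretization, Kalman-filter likelihoods with missing data,
    maximum a posteriori initialisation, Hamiltonian Monte Carlo sampling,
    BIC model comparison and explained-variance decompositions yield
    interpretable personal metrics (glucose response half-life, damping
    coefficient, meal heights, circadian amplitude and peak time) with
    posterior uncertainty. A synthetic-data generator emulating the device
    streams supports end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
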