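Package: edflow
Title: Multistate Markov Modelling of Emergency Department Patient Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the flow of patients through an emergency
    department (ED) as a five-state continuous-time Markov process (triage,
    physician management, observation, discharge, admission). Provides
    closed-form probabilistic quantities from a set of transition intensities
    (generator matrices, embedded jump chains, sojourn distributions,
    absorption probabilities, matrix-exponential transition probabilities),
    a synthetic patient-cohort generator with competing-risks exponential
    sojourns, covariate relative rates and clock-time shift structure,
    maximum-likelihood and Metropolis MCMC estimation of transition
    intensities with log-linear covariate effects and shift stratification,
    predictive dynamic state-occupancy curves, and a reproducible
    simulate-describe-fit-predict pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
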