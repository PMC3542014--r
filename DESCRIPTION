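Package: dberm
Title: Dynamic Bi-Exponential Refractory Modeling of Operant Extinction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the microstructure of free-operant behaviour
    during extinction with the dynamic bi-exponential refractory model (DBERM).
    Inter-response times are modelled as a refractory-shifted mixture of a fast
    within-bout and a slow bout-initiation Poisson process whose parameters
    decay exponentially within a session and change multiplicatively between
    sessions. The package provides the mixture density and closed-form
    moments, a Monte-Carlo simulator for single sessions and two-strain rat
    cohorts with log-normal individual heterogeneity, hierarchical Bayesian
    estimation by adaptive Metropolis-within-Gibbs with strain-level effect
    sizes, posterior-predictive checks (binned response-rate curves and
    log-survivor envelopes), and a parameter-recovery experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
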