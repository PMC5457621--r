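Package: placebosim
Title: Simulation of Quantum-Like Correlations in Two-Placebo Experiments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate a probabilistic model in which correlations
    between placebo labels and biological outcomes emerge from observer
    agreement and small random probability fluctuations. Provides the
    closed-form N-observer agreement probability and its d-parameterized
    interpolation towards classical probability, real-amplitude path calculus
    contrasting coherent (local assessment) with classical (remote assessment)
    probability, fixed-point analysis of the agreement map, a stochastic
    recurrence simulator with metastability and absorption detection,
    Monte-Carlo ensemble statistics with exact binomial branch-symmetry
    testing, and a virtual two-placebo trial generator with an exact 2x2
    association test quantifying the predicted local-significant versus
    remote-null contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
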