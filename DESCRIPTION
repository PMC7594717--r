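Package: emuflux
Title: Stationary 13C Metabolic Flux Analysis with Elementary Metabolite Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Isotopically stationary 13C metabolic flux analysis for
    glucose-limited chemostat cultures of Corynebacterium glutamicum.
    Provides an atom-mapped network model of central carbon metabolism
    with scrambling reactions and a growth-scaled biomass drain,
    elementary metabolite unit (EMU) decomposition and steady-state mass
    isotopomer distribution (MID) simulation with a full positional
    isotopomer oracle, natural isotope abundance correction, variance
    weighted least-squares flux estimation with multi-start optimization,
    chi-square model acceptance and profile-likelihood confidence
    intervals, Fisher-information based a priori tracer design, chemostat
    balance arithmetic with Pirt maintenance regression and an ODE
    bioprocess model for external rate estimation, and a synthetic data
    generator emulating the measurement structure of the labeling
    experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    deSolve,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
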