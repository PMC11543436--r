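Package: kinseg
Title: Kinetic Segregation, Lck Activity Range, and Bayesian Metamodeling of
    Early T-Cell Receptor Triggering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and probabilistic surrogate models for the nanoscale
    organization of early T-cell receptor (TCR) signaling at tight contacts with
    an antigen-presenting cell. Includes a Metropolis Monte-Carlo simulator of a
    membrane patch with TCR, CD45 and pMHC (kinetic segregation and depletion
    width), a random-walk model of activated Lck spreading from CD45 with
    stochastic deactivation (exponential decay length), a TCR phosphorylation
    model driven by the summed Lck* density field (Phos fraction and Rg ratio),
    conjugate Bayesian surrogate models fitted to simulation training grids, a
    coupled Bayesian metamodel that backpropagates observed nanoscale statistics
    into posteriors over biophysical parameters, and an affinity-scan experiment
    quantifying sensitivity and specificity of a threshold activation rule
    across pMHC:TCR association strengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
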