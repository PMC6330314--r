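Package: tiltprior
Title: Psychophysics and Bayesian Prior Modelling of the Subjective Vertical Under Body Tilt
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying visual and haptic perception of verticality in
    observers tilted 90 degrees in the roll plane, across child development.
    Implements an entropy-minimising PSI adaptive procedure for 2AFC trial
    placement, maximum-likelihood cumulative-Gaussian psychometric fitting
    (PSE and JND), maximum-likelihood visual-haptic cue combination
    predictions, and a Bayesian prior observer model in which a Gaussian
    prior over body orientation (upright, upside-down, or flat) is combined
    with age-dependent sensory likelihoods to predict Aubert (A-) and
    E-effect biases. Includes a synthetic-cohort generator so the full
    analysis pipeline can be exercised and validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
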