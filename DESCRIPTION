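Package: larvataxis
Title: Stimulus-to-Behavior Modelling of Larval Chemotaxis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrated modelling of how a single Drosophila larval olfactory
    sensory neuron (OSN) transforms odor or optogenetic light stimuli into
    firing rate, and how that firing rate modulates the probability of
    switching from a run to a turn during chemotaxis. Provides the
    incoherent feed-forward (IFF) and integral feedback (IFB) transduction
    ODE models with their quasi-steady-state analytical solution, a
    reverse-correlation linear-filter baseline, simplex-plus-gradient
    parameter estimation against peristimulus time histograms, logit-link
    generalized linear models for run-to-turn transitions with likelihood
    and bootstrap model comparison, geometric and state-machine behavioral
    classifiers, and a closed-loop agent-based larva simulator over
    synthetic radial light landscapes (exponential, volcano, well, mesa,
    linear hat).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
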