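Package: axonsim
Title: Spike Conduction Along Axons with Bounded Exponential
    Integrate-and-Fire Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compartmental simulation of action-potential generation and
    conduction along myelinated and unmyelinated axons.  Implements the
    bounded exponential integrate-and-fire (bEIF) membrane model, in which
    the spike-generating current saturates at a ceiling and a hard
    after-spike reset is replaced by an alpha-function repolarizing
    conductance, so that the model supports stable propagating spikes.
    Also provides the Wang-Buzsaki conductance-based model and the
    standard exponential integrate-and-fire model as references, a hybrid
    forward-Euler / Crank-Nicolson cable integrator, intracellular and
    extracellular point-source stimulation, conduction-velocity and f-I
    analysis, square-root scaling fits, and named parameter presets
    including low- and high-frequency auditory-nerve fibers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
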