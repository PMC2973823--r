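Package: rgcdecode
Title: Decoding Stimulus Identity and Onset Time from Retinal Ganglion Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and decoding toolkit for studying how stimulus colour
    ("what") and stimulus onset time ("when") can be read out from retinal
    ganglion cell spike trains. Generates synthetic populations of archer-fish
    retinal ganglion cells responding to brief red/green flashes via an
    inhomogeneous Poisson model, and implements linear-nonlinear (LN) readouts
    for single-cell colour discrimination and population onset detection,
    first-spike-latency and interspike-interval Bayesian classifiers, a causal
    two-stage (detect-then-discriminate) readout, spike-triggered-average
    polarity classification under Gaussian full-field flicker, and the retinal
    geometry estimates that set the scale of the encoding population.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
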