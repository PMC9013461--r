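Package: eagkit
Title: Electroantennogram Response Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("EAG", "Toolkit Developers", email = "eagkit@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing electroantennogram (EAG) recordings of
    insect antennae stimulated with odorant pulses: stimulus-locked
    segmentation, baseline correction, repeat-median averaging, running
    median denoising, responsiveness quality control, response strength
    and onset/offset latency estimation, sine-taper multitaper power
    spectral densities for pulse-tracking analysis, and Bayesian ecotype
    contrasts via flat-prior posterior simulation of linear (mixed)
    models. Includes a synthetic recording generator that emulates the
    stimulation protocol, odorant concentration dynamics, ecotype
    differences in response amplitude and kinetics, noise, drift, and
    baseline-shift artifacts, with ground truth for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
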