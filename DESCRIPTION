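Package: skittlesERP
Title: Simulation and Event-Related Potential Analysis of a Semi-Virtual
    Throwing Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying predictive and postdictive error processing
    in a semi-virtual throwing task ('Skittles'). Provides a physics
    simulator for ball flight around a central post with hit/error trial
    scoring, a synthetic electroencephalography (EEG) generator that injects
    error-related negativity (Ne/ERN) and feedback-related negativity (FRN)
    components into 1/f-plus-white background noise, an event-locked
    difference-wave pipeline (Butterworth filtering, segmentation, artifact
    rejection, baseline correction, window amplitudes), and group-level
    inference including one-sample t-tests, Cohen's d, confidence intervals,
    and JZS default-prior Bayes factors with evidence labels. Reads and
    writes BrainVision-style recordings and tab-separated trial tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
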