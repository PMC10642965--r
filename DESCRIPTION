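Package: somnoyoke
Title: Yoked-Control Sleep Deprivation and Rebound Analysis for Fly Activity Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for simulating and analysing closed-loop, yoked-control
    sleep-deprivation experiments in Drosophila. Includes a two-process-style
    generative model of fly locomotor activity (10-s maximal-velocity epochs),
    virtual deprivation engines (fixed-interval vortexing and
    inactivity-triggered tube rotation with yoked stimulus binding),
    velocity- and beam-count-based sleep scoring with a parameterizable
    inactivity criterion, P(doze)/P(wake) sleep-pressure metrics, homeostatic
    rebound quantification normalized to unperturbed controls with a
    criterion-sweep recovery surface, and a three-condition MALDI-TOF
    peak-pattern screen that separates sleep-pressure-tracking molecules from
    mechanical-stimulation artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
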