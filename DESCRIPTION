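Package: thinkaloud
Title: Multi-Coder Analysis of Timestamped Think-Aloud Session Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of think-aloud protocol
    sessions annotated independently by several coders with timestamped,
    possibly overlapping behavioral codes. Provides 5-second grid
    unitization of coded intervals, windowed reference-coder alignment
    with Fleiss' kappa for inter-rater reliability (reported as a
    per-session min/max range across reference coders), code-transition
    sequence extraction with shared (pairwise-intersection) counts,
    pre/post survey summaries (NASA task load index, confidence) with
    Welch t and F variance tests, per-coder session timeline plots, and a
    calibrated semi-Markov synthetic session generator with a
    miss/substitute/jitter/insert rater noise model for validating every
    stage without access to recorded sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
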