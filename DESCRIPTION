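Package: vocrecall
Title: Noise-Band Vocoding and Propositional Discourse-Recall Simulation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for cochlear-implant-simulation discourse-recall
    experiments: noise-band vocoding of speech (logarithmically spaced Butterworth
    analysis bands, envelope extraction, noise carriers, RMS matching), self-paced
    stimulus segmentation and counterbalanced within-subject design construction,
    three-level propositional scoring of free-recall transcripts with synonym-tolerant
    binary credit, a calibrated synthetic-data generator for recall outcomes and
    inter-segment pause durations, and the mixed-effects analysis of the semantic
    hierarchy (levels) effect with reverse model selection and likelihood-ratio tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: signal, lme4, jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
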