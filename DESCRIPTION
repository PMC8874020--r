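Package: painfuse
Title: Multimodal Physiological Pain Assessment with Decision-Level Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multimodal cold-pressor pain
    studies. Generates synthetic cohorts of nine-modality physiological
    recordings (facial action units, EEG, pupillometry, skin conductance,
    blood volume pulse, EMG, respiration, skin temperature, blood pressure)
    with configurable pain-state effects; reduces 20-second session windows
    to per-modality feature vectors (band powers, peak-based rates, means and
    slopes); classifies sessions into baseline, low pain and high pain with a
    two-stage support-vector cascade; and combines per-modality scores by a
    weighted decision-level fusion whose weights are learned with a real-coded
    genetic algorithm. Includes stratified k-fold and leave-one-subject-out
    evaluation, per-class F1 reporting, and repeated-measures ANOVA screening
    of features across pain states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
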