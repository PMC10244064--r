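Package: sleeplat
Title: Inter-Hemispheric Lateralization of Sleep EEG Markers in Focal Epilepsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects sleep slow oscillations, slow waves and spindles on
    bipolar scalp EEG, computes per-patient inter-hemispheric lateralization
    indices of nine sleep features, runs nonparametric group statistics
    (Mann-Whitney, Kruskal-Wallis with Dunn's correction, probability-of-
    superiority effect sizes), and classifies epileptic-focus laterality with
    a repeated cross-validated decision tree compared against a label-shuffle
    null. Includes a synthetic sleep-EEG cohort generator with known ground
    truth, minimal EDF input/output, and hypnogram handling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
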