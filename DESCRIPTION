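Package: dermconformal
Title: Conformal Uncertainty and Fairness Auditing for Skin-Lesion Embedding Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Split conformal prediction with a finite-sample coverage guarantee for
    multi-class skin-lesion classifiers trained on frozen foundation-model embeddings,
    together with a challenge-regulated F1-weight dynamic sampler for severe class
    imbalance, a lightweight multilayer-perceptron classifier head, and demographic-
    stratified uncertainty and fairness audits (A2 accuracy, prediction-set size
    distributions, ground-truth confidence distributions, calibration error). Includes
    a seeded synthetic embedding-cohort generator with plantable subgroup difficulty so
    the whole pipeline is testable without any image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
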