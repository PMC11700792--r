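Package: cssvm
Title: Chameleon Swarm Optimized Support Vector Machines for CT Lung
    Nodule Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for three-class CT
    lung nodule classification (normal, benign, malignant): contrast
    limited adaptive histogram equalization (CLAHE), fuzzy C-means
    intensity segmentation with region-of-interest extraction, 256-bin
    local binary pattern (LBP) texture descriptors, and a support vector
    machine whose penalty and kernel parameters are tuned by the
    chameleon swarm algorithm (CSA) under stratified K-fold
    cross-validation. A deterministic synthetic CT phantom generator
    reproduces the class structure of clinical nodule datasets so that
    every stage is testable without any external download. Evaluation
    reports per-class one-vs-rest false positive rate, specificity,
    sensitivity and recognition accuracy with macro averages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
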