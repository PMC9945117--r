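Package: virionRF
Title: Phage Virion Protein Classification from Sequence Composition Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Encodes protein sequences with four composition-based
    descriptors (amino acid composition, composition of k-spaced amino
    acid pairs, dipeptide composition, and dipeptide deviation from
    expected mean), concatenates them into a single feature vector, and
    trains and cross-validates a random-forest classifier (with linear
    discriminant, support vector machine, and decision tree baselines)
    for binary phage virion versus non-virion protein prediction.
    Reports sensitivity, specificity, accuracy, Matthews correlation
    coefficient, F1 and ROC curves, and ships a synthetic two-class
    sequence generator with controllable composition and motif signal
    for end-to-end testing without external benchmark data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    randomForest,
    MASS,
    e1071,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
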