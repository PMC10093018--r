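Package: mammofuse
Title: Haze-Reduced Enhancement, Feature Fusion and Equilibrium-Jaya
    Feature Selection for Mammogram Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for mammogram computer-aided diagnosis:
    haze-reduction-based local-global contrast enhancement built on the dark
    channel prior, lossless rotation/flip augmentation, deterministic
    filterbank feature extraction with a pluggable deep-backbone contract,
    serial feature fusion with a binomial-probability activation rule, a
    hybrid Equilibrium-Optimizer/Jaya wrapper feature selector with Regula
    Falsi termination and 1-nearest-neighbour fitness, and a classifier
    benchmark harness reporting macro-averaged sensitivity, precision, F1,
    AUC, accuracy and false-negative rate. Includes seeded synthetic-data
    generators for hazed lesion images and labelled feature matrices so every
    stage is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    e1071,
    nnet,
    randomForest,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
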