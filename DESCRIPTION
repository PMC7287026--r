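Package: ommaQuant
Title: Automated Quantification of Rough-Eye Degeneration in Drosophila
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated quantification of the Drosophila rough-eye
    phenotype from bright-field photographs. Segments the compound-eye
    region of interest with white top-hat morphology, quantile
    thresholding, a Weiszfeld L1-median centroid and a confidence
    ellipse; summarises each region with a 125-dimensional histogram of
    oriented gradients; trains and evaluates classical classifiers
    (RBF-kernel SVM, decision tree, AdaBoost decision tree, random
    forest) over five phenotype classes; and converts posterior class
    probabilities into a scalar eye-regularity index (IREG) ranging
    from 0 (full degeneration) to 1 (healthy eye). Includes a synthetic
    compound-eye image generator with controllable disorder so the
    whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    e1071,
    rpart,
    randomForest,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
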