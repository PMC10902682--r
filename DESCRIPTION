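Package: sig2image
Title: Sequence-to-Image Encoding and Attention-Based Classification of
    Nanopore Current Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts unequal-length 1-D nanopore blockade-current signals
    into fixed-size 2-D images via piecewise aggregate approximation,
    min-max scaling, polar encoding and Gramian angular fields (summation
    and difference forms), with Markov transition field and recurrence
    plot alternatives.  Includes a transformer encoder-decoder classifier
    operating on image patches, a convolutional ablation network, a
    synthetic signal generator emulating analyte-morphology and peak-train
    barcode tasks, and an evaluation harness with stratified
    cross-validation, micro-averaged ROC/PR curves and
    normality-plus-t-test run comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
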