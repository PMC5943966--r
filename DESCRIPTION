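Package: svmrfeoa
Title: Overlap-Aware Support Vector Machine Recursive Feature Elimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature selection for high-dimensional, small-sample biological
    data (microarray and other omics matrices) by recursive feature
    elimination with a linear support vector machine. Beyond the classic
    accuracy-driven SVM-RFE, the package implements two overlap-aware
    selectors: one scores each candidate feature subset by combining
    cross-validated accuracy with the average normalized class-overlap degree
    Nr(x) of the training samples, and a modified variant that additionally
    screens out heavily overlapping samples before each SVM fit. Includes a
    per-sample k-nearest-neighbour overlap profiler, a repeated stratified
    cross-validation evaluation harness reporting accuracy, sensitivity and
    specificity, a synthetic data generator for the high-dimension
    small-sample regime, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
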