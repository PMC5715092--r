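Package: nanowell
Title: Deep-Learning Cell Counting in Nanoliter-Well Microscopy Images
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Counts viable cells in nanoliter-well grayscale microscopy
    images by classifying each well into 0, 1, 2 or more-than-2 cells with
    an 18-layer convolutional neural network (8 convolution, 4 max-pooling,
    4 local-response-normalization and 2 fully connected layers), trained
    by stratified mini-batch stochastic gradient descent with early
    stopping. Includes a confidence-threshold triage ("enhanced system")
    that routes low-confidence wells to human review or exclusion, a
    synthetic plate generator with Poisson well occupancy for end-to-end
    benchmarking, and the evaluation arithmetic for technician-versus-
    classifier confusion tables, censored-Poisson occupancy fits and
    concordance comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
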