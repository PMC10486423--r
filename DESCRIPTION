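Package: ecgwo
Title: Entropy-Controlled Grey Wolf Optimization for Deep-Feature
    Fusion and Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Serial fusion of deep-feature blocks (as extracted from the
    fully-connected and average-pooling layers of pretrained convolutional
    networks), wrapper feature-subset selection by an entropy-controlled
    grey wolf optimizer with a Shannon-entropy fitness, and a stratified
    hold-out classification harness reporting accuracy, sensitivity,
    specificity, false-negative/false-positive rates and F1.  Includes a
    seeded synthetic generator of multi-block feature matrices with known
    informative, redundant and noise structure so the whole pipeline is
    testable without images or pretrained weights.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    e1071,
    class,
    rpart,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    arrow,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
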