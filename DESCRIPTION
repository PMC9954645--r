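Package: dssl
Title: Dual-Encoder Semi-Supervised Classification for Neuropsychological Score Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised three-class classification (normal control, mild
    cognitive impairment, Alzheimer's disease) from itemized neuropsychological
    test scores when only a small number of diagnoses are available. Implements
    a dual semi-supervised learning (DSSL) model: two small one-dimensional
    convolutional encoders with different pooling operators produce two
    representations of each subject, a difference regularizer pushes the two
    representations apart, and the two prediction heads supply each other with
    confidence-thresholded pseudo-labels for consistency training on unlabeled
    subjects. Also provides Pearson-correlation feature ranking, a synthetic
    score-table generator with class-graded features, held-out and stratified
    k-fold evaluation with macro-averaged metrics, pseudo-label quality
    diagnostics (passing and impurity rates), a labeled-set stability
    experiment, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
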