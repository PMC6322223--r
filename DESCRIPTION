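Package: weaktext
Title: Weakly Supervised Clinical Text Classification with Deep Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clinical text classification paradigm built on weak supervision:
    rule-based labeling functions (regular-expression rule sets for smoking
    status and proximal femur fracture extraction) generate weak labels,
    documents are represented by mean-pooled word embeddings (with tf-idf and
    topic-mixture baselines), and classifiers (linear SVM, random forest,
    multilayer perceptron, text CNN) are trained on the weak labels and
    evaluated against gold annotations and against the rules themselves.
    Includes a simulation harness for the weak-supervision loss-bound theory
    (weak-label distribution, weak and true regularized logistic losses, and
    an empirical check of the |L(w) - L_phi(w)| bound) and a seeded synthetic
    clinical-note generator (negated and misspelled cue phrases,
    semi-structured lines, cross-sentence keyword/modifier splits, clustered
    synthetic embeddings) so the whole pipeline is testable without access to
    protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Matrix,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
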