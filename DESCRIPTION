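Package: stss
Title: Self-Training in the Significance Space of Support Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised learning for severely imbalanced, high-dimensional,
    sparse multi-class classification. Implements self-training in the
    significance space of support vectors (STSS): each round relabels the
    training set into support vectors ("significant") versus the rest, trains a
    significance classifier on that binary view, queries the significant subset
    of a data pool, and augments the training set with confidently labeled
    examples. A two-phase framework first balances the training data by
    informative-subset selection against the majority class, then exploits an
    unlabeled pool by self-labeling. Includes one-vs-rest linear SVM base
    classifiers with Platt-calibrated confidences, under-sampling,
    inverse-frequency class weighting and traditional self-training baselines,
    a sparse svmlight reader/writer, a synthetic generator emulating biomedical
    event-extraction edge-detection data, per-class precision/recall/F
    reporting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    jsonlite,
    methods,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
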