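Package: probioscreen
Title: Information-Theoretic Genome Features and Machine Learning for
    Probiotic Bacteria Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates probiotic from non-probiotic bacteria using
    information-theoretic and Chargaff-parity statistics computed on
    annotated genomes. Provides per-sequence scores (Shannon entropy,
    topological entropy, two Chargaff second-parity-rule scores), a GenBank
    flat-file reader that extracts CDS/rRNA/tRNA/ncRNA element sequences, a
    61-feature genome encoder, a synthetic annotated-genome cohort generator
    with planted tRNA information-content effects, recursive feature
    elimination and repeated stratified cross-validation over four
    classifier families (logistic regression, random forest, RBF support
    vector machine, single-hidden-layer neural network), permutation feature
    importance, and a full binary-classification evaluation suite (Cohen's
    Kappa, MCC, F1, exact binomial confidence intervals, rank-based AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    nnet,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
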