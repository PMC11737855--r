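Package: ssnvStack
Title: Stacked Ensemble Scoring of Driver Synonymous Single-Nucleotide Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores synonymous single-nucleotide variants (sSNVs) as cancer
    drivers versus passengers from sequence representation. Encodes 101-bp
    allele-specific windows into DNA-shape (pentamer lookup), physicochemical
    (NCP, EIIP, PCP, one-hot) and embedding-derived feature groups together
    with alt-minus-ref allele-difference features; screens feature groups by
    cross-validated discriminative power; ranks surviving features by four
    importance measures (random-forest impurity, gradient-boosting gain,
    regularized boosting gain, mRMR) with importance-ranked forward subset
    search; and combines five tree-based base learners through out-of-fold
    probability stacking under a logistic-regression meta-classifier.
    Includes a recurrence-based dataset builder (labelling, redundancy
    filtering, proximity pairing, stratified splitting), a full evaluation
    suite (precision through MCC, ROC/PR areas, cumulative effect risk), a
    deterministic synthetic-fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    e1071,
    jsonlite,
    ranger,
    Rcpp,
    rpart,
    stats,
    utils,
    vcfR,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
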