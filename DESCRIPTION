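Package: combipath
Title: Predicting Effective Drug Combinations from Pathway-Affect Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts effective pairwise drug combinations from per-drug gene
    expression signatures. Each drug's significantly changed gene set (two-sample
    t-test on treated versus control replicates) is mapped onto disease pathway
    gene sets to give a binary pathway-affect fingerprint. Drug pairs are encoded
    either as a linear-addition fold-change vector over shared genes or as binary
    indicators of pathway-pair patterns scored by their frequency enrichment in
    known effective combinations relative to random pairings. Feature selection
    (greedy mRMR for continuous features, frequency-score thresholding for
    patterns) feeds two-class and one-class support vector machines with grid
    search over kernel parameters, and a naive Bayes classifier trained by
    mergeable sufficient statistics so partitioned fits aggregate to the exact
    sequential model. Evaluation covers k-fold and leave-one-out cross-validation
    and repeated stratified train/test splits, plus a fully seeded synthetic-data
    generator with planted pathway-pair enrichment for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
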