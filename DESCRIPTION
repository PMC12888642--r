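Package: fedforest
Title: Federated Ensemble Learning for Random Forests on Multi-Site Clinical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Horizontal federated learning for random forests on tabular
    clinical cohorts held by multiple sites. Trains one probability forest per
    site, aggregates per-site predicted probabilities by weighted averaging
    under five schemes (unweighted, sample size, positive-class count,
    minority-class count, and a Shannon-evenness-based maximum-possible-
    diversity weight), and benchmarks all models with a shared stratified
    k-fold protocol reporting AUROC with fold-wise confidence intervals and
    Youden-index operating points. Includes a seeded synthetic multi-site
    cohort generator emulating an eleven-hospital delirium cohort's size and
    class-imbalance profile, and delimited-file I/O for per-site tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ranger,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
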