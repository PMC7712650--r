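Package: bsmselect
Title: Bootstrap SVM-MRMR Gene Selection for Two-Class Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gene selection for two-class (case/control) expression studies
    by fusing a maximum-relevance minimum-redundancy (MRMR) filter with
    linear support-vector-machine (SVM) weights through a quadratic rank
    integration score, and assigning each gene a significance value via a
    bootstrap subject-resampling signed-rank test with Hochberg step-up
    correction.  Includes evaluation utilities (sliding-window
    classification accuracy, QTL containment enrichment, GO Jaccard
    distance), seeded synthetic-data generators, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    GenomicRanges,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
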