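Package: mrmrifs
Title: Two-Stage mRMR and Incremental Feature Selection for Expression Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies compact gene-expression biomarker panels for a binary
    phenotype (e.g. KRAS mutation status of lung cancer cell lines) with a
    two-stage procedure: genes are first ranked by minimal-redundancy
    maximal-relevance (mRMR) on mutual information over three-state
    discretized expression, then the panel size is chosen by incremental
    feature selection (IFS) -- evaluating classifiers on growing rank-order
    prefixes under leave-one-out cross-validation and picking the prefix with
    the best Matthews correlation coefficient. Ships adapters for six
    classifier families (SVM, 1/3/5-nearest-neighbour, decision tree, neural
    network), readers for delimited and GEO series-matrix expression tables,
    a synthetic expression-data generator with informative and redundant gene
    blocks, and an end-to-end pipeline with run manifests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    ggplot2,
    jsonlite,
    nnet,
    rpart,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
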