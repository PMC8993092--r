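Package: panelmiR
Title: Serum Small-RNA Biomarker Panels via Differential Expression and
    Nested Cross-Validated Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for circulating small-RNA biomarker
    discovery from count matrices: TMM normalization and negative-binomial
    quasi-likelihood differential expression, a nested leave-one-out
    cross-validation SVM classifier with in-fold feature selection and a
    panel-size saturation sweep, multi-database miRNA-to-gene target
    aggregation with support ranking, and hypergeometric term enrichment
    with step-down (Holm) adjustment. A synthetic-data module generates
    count matrices, target edge lists and annotation tables with the
    statistical structure the analysis assumes, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    limma,
    e1071,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
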