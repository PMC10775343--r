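Package: chemfunc
Title: Patent-Derived Chemical Function Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses text-derived chemical function datasets:
    extraction of short functional labels from patent text with pluggable
    summarization and embedding backends, embedding-based vocabulary
    consolidation by density clustering with an epsilon sweep, per-label
    structural-congruence tests (maximum Tanimoto similarity against
    resampled nulls with Benjamini-Hochberg FDR control), label
    co-occurrence graphs with modularity communities, and multi-label
    structure-to-function classifiers used for functional-profile
    annotation and ranked label-guided molecule retrieval. Includes a
    synthetic corpus generator so the full pipeline runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    glmnet,
    ranger,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    pROC,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
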