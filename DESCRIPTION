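Package: lcembed
Title: Life-Course Embeddings of Register Event Histories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for exploring population register data as a semantic
    landscape. Individual-level event histories (diagnoses, prescribed
    medications, procedures, childhood adversities) are converted into
    chronologically ordered "life-course sentences", global event
    embeddings are trained with a skip-gram architecture and hierarchical
    softmax, and query terms such as sleep-related codes are explored via
    cosine-similarity nearest neighbors, UPGMA and consensus clustering,
    two-dimensional landscape projection with kernel density estimation,
    neighborhood networks, and age-specific incidence rates with
    within-term quantile categorization. Includes a synthetic
    register-cohort generator with planted co-occurrence communities and
    embedding-stability diagnostics (subsample retraining, cross-algorithm
    agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    cluster,
    mclust,
    igraph,
    ape,
    MASS,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
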