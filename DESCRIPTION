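Package: snowsem
Title: Semantic Networks of Risk from Mini-Snowball Word Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses semantic networks of a focal concept (such
    as "risk") from two-level mini-snowball word-association data. Responses
    to a focal cue (level 1) are characterised by the frequency profiles of
    the associations they elicit in turn (level 2); profiles are compared
    with the weighted Jaccard (Ruzicka) similarity, represented as a
    weighted network, and partitioned into semantic components with a seeded
    multi-restart Louvain algorithm. Downstream analyses cover bootstrap
    cluster stability, sentiment propagation from a lexicon over associates,
    similarity of components to the focal concept, cross-language network
    comparison, age and gender differences in retrieval frequencies, and
    cross-validated elastic-net prediction of self-reported risk-taking
    propensity with corrected resampled t-tests. A synthetic-data generator
    with planted components supports end-to-end testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
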