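Package: vcprofiles
Title: Vertex Collocation Profiles for Multirelational Link Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes vertex collocation profiles (VCPs): exhaustive,
    isomorphism-collapsed counts of how a vertex pair is jointly embedded in
    all n-vertex, r-relation, optionally directed subgraphs of a network.
    Provides the subgraph addressing and canonicalization machinery (static
    and memoized dynamic subgraph-to-element mappings), optimized
    neighborhood-bound counting algorithms for 3- and 4-vertex profiles,
    temporal snapshot encoding that turns longitudinal event streams into
    multirelational graphs, synthetic graph and event-stream generators, and
    a supervised link-prediction pipeline with information-gain feature
    ranking and AUROC/AUPR evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
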