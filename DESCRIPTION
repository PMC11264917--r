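Package: RxnRebalance
Title: Rebalancing of Stoichiometrically Incomplete Chemical Reactions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Curation of reaction databases by imputing the co-reactants and
    co-products that are missing from unbalanced reaction SMILES. Non-carbon
    compounds are inferred by a depth-first search over an ion-centric rule
    library applied to element-count difference dictionaries; missing
    carbon-containing compounds are reconstructed by an iterative ensemble of
    maximum common subgraph alignments between the reactant and product
    molecular graphs, followed by configurable expand and merge rules. A
    gradient-boosted confidence model scores graph-based imputations, and an
    evaluation harness measures success rate and exact-canonical accuracy on
    artificially unbalanced fixture reactions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    ChemmineOB,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
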