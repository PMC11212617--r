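Package: biblioRank
Title: Bibliometric Novelty-Importance Scoring and Pareto Ranking of
    Target-Disease Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes literature-derived Novelty and Importance scores for
    protein targets and their disease associations from text-mined
    publication mention tables, propagates publication support through the
    Disease Ontology is_a hierarchy, ranks associations by non-dominated
    (Pareto) sorting over novelty and importance, and exports ranked,
    annotated association tables. Includes a synthetic corpus generator
    with independent ground-truth scoring for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
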