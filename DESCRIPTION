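Package: linkscreen
Title: Network-Guided Drug Repositioning from Differential Expression Link Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores gene/protein interactions by disease-induced expression
    change (LinkScore, InteractionScore and single-gene fold-change
    heuristics), filters each experiment's links to the extreme-quantile
    relevant set, inverts the disease signature and compares it against a
    library of drug-perturbation signatures by link-set Jaccard overlap and
    Pearson correlation of LinkScores on the union of selected links, ranks
    candidate repositioning drugs, and renders the top-regulated differential
    subnetworks with a green-white-red regulation colour map. Includes a
    synthetic-data generator that emulates a sparse typed interaction
    network, a two-module disease perturbation and a drug library with a
    planted signature reverser, so the full pipeline runs and can be
    validated without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
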