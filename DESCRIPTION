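Package: msconn
Title: Graph Convolutional Classification and Nodal Statistics for
    Structural Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing structural brain connectivity matrices
    (tractography fiber counts between parcellated gray-matter regions) in
    longitudinal clinical cohorts such as multiple sclerosis studies.
    Provides a synthetic cohort generator with group-graded connectome
    degradation, proportional edge thresholding, binary and weighted local
    graph metrics (degree/strength, clustering coefficient, local
    efficiency, betweenness centrality), a single-layer graph convolutional
    network classifier trained with Adam and early stopping, stratified
    subject-level cross-validation with macro precision/recall/F-measure,
    exact Wilcoxon-Mann-Whitney comparisons, and per-node linear
    mixed-effects group contrasts with post-hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    lmerTest,
    emmeans,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
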