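Package: netsweep
Title: Sparsity-Swept Graph Topology Analysis of Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for resting-state functional-connectome topology
    analysis: Pearson/Fisher-z connectivity from region-wise BOLD time series,
    proportional-threshold binarization across a sparsity sweep, global and
    nodal graph metrics including a nodal small-world propensity index with
    random-network nulls, trapezoidal area-under-curve summaries across the
    sweep, and group inference by edgewise permutation tests with
    Benjamini-Hochberg correction, network-based-statistic component
    family-wise-error control, and two-sample tests on AUC metrics. Includes a
    seed-deterministic synthetic-data generator emulating a two-group
    pharmaco-fMRI study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
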