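Package: fconn
Title: Group Resting-State Functional Connectivity and Graph-Metric Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end group analysis of resting-state functional
    connectivity time series: CompCor-style nuisance denoising with
    motion/outlier regression and band-pass filtering, seed-based
    connectivity maps with permutation cluster-extent inference,
    large-scale-network connectivity aggregation, cluster-atlas overlap
    scoring, and density-swept nodal graph metrics (degree, strength,
    betweenness, eigenvector centrality) summarized by area under the
    curve with bootstrap max-t family-wise inference. Includes a
    synthetic two-group data generator with planted connectivity effects
    for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
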