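Package: richclubnet
Title: Weighted Rich-Club, Global Topology and Network-Based Statistic
    Analysis of Structural Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for group-level analysis of weighted structural brain
    networks built from probabilistic tractography. Implements voxel-count
    normalization of connectivity-probability matrices, weighted rich-club
    coefficient curves against weight-reshuffle null models, rich-club /
    feeder / local edge classification with connective average strengths,
    global weighted graph metrics (clustering, path length, efficiency,
    fault-tolerant efficiency, strength, assortativity, density) with
    small-world normalization against degree-preserving rewired nulls, the
    network-based statistic (NBS) with max-component permutation FWER
    correction, covariate-adjusted permutation tests, ANCOVA with LSD post
    hoc comparisons, partial correlations and stepwise regression for
    brain-behaviour analysis, and a synthetic cohort generator with planted
    hub structure and group effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    emmeans,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
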