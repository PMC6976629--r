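Package: arginet
Title: Multi-Omics Analysis of Arginine-Dependent Multinucleated Giant Cell
    Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for the computational stages of a
    multi-omics study of arginine-dependent multinucleated giant cell
    (osteoclast) formation: expression filtering and log-CPM
    normalisation with moderated differential-expression calls, a
    rank-sum pathway permutation test with empirical p-values and
    Bonferroni correction, label-free proteomics processing
    (detection filtering, left-censored imputation, coefficient-of-variation
    discordance filtering, s0-moderated permutation-FDR testing),
    stable-isotope tracer arithmetic on isotopologue tables, and
    multi-omics network integration via a prize-collecting Steiner tree
    heuristic with a connected-subgraph randomisation null. Every input
    the pipeline consumes can be simulated with known ground truth, so
    all stages are testable without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
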