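Package: dolloscan
Title: Hierarchical Loss Mapping and Small-RNA Cluster Signatures on a Fixed Phylogeny
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps losses of ancestrally present binary characters (microRNA
    families, metazoan core genes, morphological traits) and gains of novel
    characters onto a fixed rooted tree under Dollo irreversibility, and
    summarises per-branch, per-tip and per-clade event counts. Provides
    cross-layer association statistics (ordinary least squares, Spearman
    partial rank correlation controlling a covariate, hypergeometric
    over-representation with Benjamini-Hochberg adjustment), expected-
    complement accounting by phylogenetic node of origin, and piRNA signature
    statistics from mapped small-RNA reads in BED format: length
    classification, ping-pong 5' overlap profiles, 2-kb window densities,
    cumulative coverage and a permutation clustering-ratio statistic. Seeded
    synthetic-data generators emulate the statistical structure of each input
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    stats,
    utils,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
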