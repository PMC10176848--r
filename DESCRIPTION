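Package: MucosaNet
Title: Co-Occurrence Network Analysis of Lung Mucosa-Colonizing Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers resampling-supported co-occurrence networks from
    genus-level abundance tables of lung mucosa-colonizing bacteria,
    partitions the positive-correlation subgraph into communities under a
    three-principle rule, compares per-community degree statistics across
    clinical strata, subtracts negative-control contamination, tests
    differential abundance with false discovery rate control, and builds
    thresholded bipartite correlation networks between taxa and clinical
    factors (peripheral-blood immune cells and cancer markers). Ships a
    planted-structure synthetic data generator emulating a healthy/NSCLC
    cohort so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    igraph,
    jsonlite,
    vegan,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'abundance.R'
    'metadata.R'
    'network.R'
    'decontam.R'
    'cooccurrence.R'
    'communities.R'
    'groupstats.R'
    'envcorr.R'
    'synthetic.R'
    'pipeline.R'
    'utils.R'
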