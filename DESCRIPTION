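Package: dyncomplex
Title: Protein Complex Detection from Dynamic TAP-Aware Weighted Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects protein complexes from a protein-protein interaction (PPI)
    network in four phases: edge weighting that fuses tandem affinity
    purification (TAP) purification scores with Gene Ontology (GO) semantic
    similarity (SimGIC), Lamarckian memetic biclustering of time-course gene
    expression to carve the network into dynamic subnetworks, core-attachment
    complex detection on each subnetwork guided by weighted clustering
    coefficients, and a similarity-driven aggregation post-processor that
    merges redundant complexes via their common part. Includes readers and
    writers for the flat-file formats involved (edge lists, TAP score tables,
    expression matrices, OBO/GAF, complex catalogs), Jaccard-based benchmark
    evaluation (precision/recall/F-1), and a synthetic data generator with
    planted complexes and planted expression biclusters for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
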