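Package: intrinsicConnectome
Title: Intrinsic Geometry of Weighted Brain Connectomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs, quantifies and perturbs the intrinsic geometry of a
    weighted structural brain connectome. Nodes are represented by their
    vectors of graph distances (shortest paths on edge lengths equal to the
    inverse connection weight) to all other nodes, embedded into low
    dimensions by classical multidimensional scaling and by Isomap with
    iterative neighbourhood growth, validated through the correlation between
    nodal path length and distance to the embedding centre, and stress-tested
    by targeted and Monte-Carlo random node-removal simulations scored with a
    cohesion statistic (the mean distance of embedded nodes to the embedding
    centre). Also provides the recursive atlas-parcellation upsampling that
    bisects labelled regions perpendicular to their principal axes, and
    synthetic generators (modular connectomes with a planted rich club, Swiss
    rolls, label volumes) for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
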