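Package: chesmapr
Title: Chemical Space Mapping of Small-Molecule Datasets in 3D
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maps small-molecule datasets into three-dimensional space so
    that spatial proximity reflects feature similarity. Reads SD-files,
    SMILES lists and CSV feature tables; mines linear structural fragments
    (FP2-style simple paths up to a configurable atom count) and matches
    SMARTS patterns to build binary structural features; computes simple
    physico-chemical descriptors; partitions compounds with cascade k-means
    selected by the Calinski-Harabasz criterion (plus hierarchical and
    farthest-first alternatives); embeds the feature matrix into 3D via
    principal components, Sammon mapping or SMACOF majorization; aligns
    cluster members on a maximum common subgraph or largest shared fragment
    by Kabsch superposition; and exports an annotated scene (JSON and
    SD-file) for downstream viewers.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    ChemmineOB,
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
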