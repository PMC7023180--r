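Package: csaclust
Title: Colorimetric Sensor-Array Simulation and Hierarchical Cluster Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates bacteriophage-based structural-color sensor-array
    chips with known ground truth, extracts per-cell delta-RGB response
    patterns from pre/post exposure chip images, computes a color-distance
    matrix over response patterns, and performs agglomerative hierarchical
    clustering with Ward (error-sum-of-squares increment) linkage via the
    Lance-Williams recurrence to discriminate chemical classes (for example
    estrogens versus antibiotics) by their color-change patterns. Includes
    dendrogram utilities (tree cutting, cophenetic distances, Newick
    export), nearest-pattern classification of unknown samples, and a
    command-line pipeline driver with full run provenance.
License: MIT
Encoding: UTF-8
Imports:
    png,
    yaml,
    mclust,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
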