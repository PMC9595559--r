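Package: cnaseg
Title: User-Guided and Automated Segmentation of Tumor Copy-Number Bin Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless engine for segmenting multi-sample tumor read-depth-ratio
    (RDR) and B-allele-frequency (BAF) bin data. Provides a tab-separated bin
    dialect reader/writer with validation, hybrid global/local segmentation
    (Gaussian mixture model followed by per-chromosome Viterbi decoding of a
    hidden Markov model built on the fitted components), scripted
    cluster-editing operations with a replayable operation log, cluster
    analytics (centroids, downsampled silhouette coefficients, inter-cluster
    distances), purity/ploidy-anchored integer allele-specific copy-state
    inference with driver-gene classification, clustering-agreement metrics
    (adjusted Rand index, V-measure, silhouette), and a synthetic multi-clone
    tumor simulator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    igraph,
    jsonlite
Config/testthat/edition: 3
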