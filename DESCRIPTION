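Package: crowdspot
Title: Crowdsourced Spot Annotation Consensus and Spot-Calling Parameter
    Tuning for In Situ Transcriptomics Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preparing in situ transcriptomics images for
    point-annotation, merging redundant (crowdsourced) point annotations
    into consensus spot locations with cluster-level quality control, and
    using consensus or expert annotations to extract, tune and validate
    spot-calling parameters. Includes a synthetic smFISH-like image
    simulator with controlled spot size, count, signal-to-noise ratio and
    spacing, and a simulated-annotator model, so the whole pipeline is
    testable end-to-end without a crowdsourcing service. Detection is
    based on scale-normalized Laplacian-of-Gaussian filtering; consensus
    building uses affinity-propagation clustering followed by cluster-size
    thresholding and multi-click clump detection with k-means declumping;
    point sets are compared by one-to-one matching under a correctness
    radius (precision, recall, Jaccard).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
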