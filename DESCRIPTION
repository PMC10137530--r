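Package: glyolite
Title: Global-Local Lightweight Single-Stage Object Detection Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, profiles and exercises a family of anchor-based
    single-stage detection architectures for fallen-person detection:
    contextual-transformer (CoT) attention blocks, the parameter-free
    energy-based SimAM attention layer, a convolutional stem replacing the
    focus module, and structurally re-parameterizable rep blocks that
    collapse multi-branch training-time convolutions into single 3x3
    convolutions for deployment. Networks are assembled from declarative
    layer tables, profiled under an analytic parameter/FLOP calculus and a
    two-ops-per-multiply-accumulate profiler convention, and supported by
    K-means++ anchor generation, a binary cross-entropy based detection
    loss, precision/recall/F1 and mAP@0.5 evaluation, TOPSIS composite
    model ranking, and a synthetic single-class detection dataset
    generator with a head-only training loop for desk-scale smoke tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    yaml,
    jsonlite,
    png,
    xml2,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
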