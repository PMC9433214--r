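Package: SwarmSeg
Title: Comparative Medical Image Segmentation with Swarm Intelligence and
    Convolutional Mask Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A benchmarking framework for intensity-based medical image
    segmentation. Implements six segmentation pipelines sharing one
    preprocessing front-end (grayscale conversion, clip-limited adaptive
    histogram enhancement, dermoscopic hair removal): fuzzy C-means,
    K-means, both hybridized with particle swarm optimization of the
    cluster centers, and both refined by a small convolutional network
    trained on paired ground-truth masks. Ships a synthetic phantom
    generator with exact ground truth emulating MRI, microscopy,
    dermoscopy and CT difficulties, and a nine-metric evaluation suite
    (precision, recall, F-measure, accuracy, error, MCC, Dice, Jaccard,
    wall time) with benchmark aggregation and a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
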