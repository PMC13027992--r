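Package: dualseg
Title: Consistency-Driven Dual-Teacher Semi-Supervised Semantic Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised semantic segmentation for microscopy images with
    scarce pixel-level annotation, built around a heterogeneous dual-teacher
    mean-teacher framework. A deep main teacher (updated as an exponential
    moving average of the student) and a gradient-trained shallow auxiliary
    teacher provide complementary predictions on unlabeled images; an
    attention-guided feature-fusion branch produces a third prediction; and a
    multi-source consistency-guided pseudo-label filter with dynamic per-class
    quantile thresholds partitions unlabeled pixels into hard pseudo-labels,
    confidence-weighted soft pseudo-labels, and ignored pixels. Includes a
    deterministic synthetic zooplankton-like microscopy image generator, a
    full training loop with ablation switches, segmentation metrics (mIoU,
    precision, recall, F1, Dice), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    optparse,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
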