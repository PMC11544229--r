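Package: myophase
Title: Muscle Recovery-Phase Classification from HE-Stained Slides via
    Learning from Label Proportions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments cells in hematoxylin-eosin stained whole-slide images of
    regenerating skeletal muscle and classifies each cell into one of four
    recovery phases (stable, early, mid, late) using a three-layer perceptron
    trained only from day-level class proportions (learning from label
    proportions, LLP).  Includes whole-slide tiling and reassembly, a
    deterministic classical segmentation backend with a pluggable adapter
    contract, a handcrafted cell-crop descriptor with a pluggable deep
    feature-extractor hook, bag construction and the KL proportion loss, a
    pseudo-label baseline, sigmoid-anchored recovery scoring, the full
    object-level and class-level evaluation protocol (mean IoU, F1 at an IoU
    threshold, confusion matrices, KL cross-validation, Mann-Whitney U,
    Cliff's delta), and seeded synthetic tissue-phantom and feature-set
    generators so the whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
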