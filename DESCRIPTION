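Package: toothopt
Title: Prior-Knowledge Candidate Optimization for Tooth Detection in
    Dental Panoramic Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Refines tooth-numbered bounding-box detections on dental
    panoramic radiographs. Given per-tooth candidate boxes with confidence
    scores (e.g. from a CNN detector), selects for each of the 32 permanent
    tooth positions either one candidate or "missing" so as to maximize a
    combined confidence and anatomical positional-relationship score, using
    a greedy coordinate-ascent search with an exhaustive oracle for
    verification. Includes detection evaluation metrics (IOU matching,
    precision, recall, F1, per-class average precision and mAP), a seeded
    synthetic detector-output simulator for testing without radiographs,
    COCO-style JSON and CSV readers/writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
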