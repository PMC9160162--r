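Package: endoquant
Title: Tile-and-Stitch Detection and Morphometrics of Endosymbionts in
    Host-Cell Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counting and phenotyping of intracellular bacterial
    endosymbionts (such as Buchnera aphidicola in aphid bacteriocytes)
    from single-channel fluorescence micrographs. Large images are cropped
    into overlapping 512-pixel tiles, a pluggable per-tile object detector
    is applied, and per-tile detections are stitched back into global
    coordinates with median-size filtering and IoU-based duplicate
    suppression. Includes readers and writers for labelme and COCO polygon
    annotations, a precision-recall/average-precision evaluation procedure
    with equal-count score bins, per-cell morphometrics (density, occupied
    cytoplasm fraction, object size), a variance-routed statistical test
    battery with compact letter displays, and a synthetic-scene generator
    that renders DAPI-like toroidal objects with exact ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    car,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
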