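Package: limbstitch
Title: Feature-Based Stitching of Full-Length Lower-Limb Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Automatic mosaicking of hip, knee and ankle radiograph tiles
    into a single full-length lower-limb image. Bone contours are
    extracted with a Canny edge detector, consecutive tiles are aligned
    by exhaustively minimizing a symmetric edge-matching cost built on
    nearest-edge Euclidean distance maps, and the overlap regions are
    fused by convex combination of multilevel wavelet coefficients.
    Includes a synthetic leg-phantom generator with known tile offsets
    and programmed hip-knee-ankle (HKA) angle for ground-truth
    validation, plus utilities to measure the HKA angle and compare
    angle sets between stitching sources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
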