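Package: peachlut
Title: Color Look-Up-Table Segmentation and Tracking of Red Peaches in Orchard Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Real-time-style fruit detection for precision agriculture, built
    around three-dimensional segmentation look-up tables (LUTs) indexed by the
    16-bit RGB565 color code. Two methods build the LUT: linear color models
    (line segments with a distance tolerance in RGB space, fitted by principal
    axis regression from labeled pixels) and a 3D color histogram of fruit
    pixels thresholded into a binary classifier. Includes byte and bit-packed
    LUT layouts, camera acquisition simulation (2x-subsampled normal mode and
    cropped zoom mode on a 640x480 sensor), threshold-rule segmentation
    baselines, centroid computation and a normal/zoom tracking state machine,
    a seeded synthetic-orchard scene generator with exact per-fruit occlusion
    bookkeeping, and an evaluation protocol reporting area relative error and
    noisy-pixel fractions stratified by illumination and occlusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
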