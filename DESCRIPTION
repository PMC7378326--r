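Package: orchardyield
Title: Per-Tree Fruit Counting and Yield Maps from Georeferenced Orchard Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline turning a georeferenced top-view orchard raster and
    per-tree coordinates into yield maps: circular per-tree cropping, fruit
    detection and counting (pluggable detector contract with a deterministic
    colour-blob reference detector), bounding-box evaluation against PASCAL VOC
    ground truth (precision, recall, F1, accuracy), visible-to-total count
    extrapolation by calibration regression, and per-tree / per-row yield map
    layers. Includes a synthetic orchard scene generator with known ground truth
    so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    foreign,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
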