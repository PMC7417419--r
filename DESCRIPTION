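Package: ricepheno
Title: Image-Based Drought Phenotyping for Rice Shoots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies drought responses of rice shoots from multimodal
    phenotyping imagery and gravimetric pot weighing. Segments the plant from
    side- or top-view RGB images and computes shape descriptors (projected
    area, bounding extents, convex hull area, compactness, eccentricity,
    center of mass, perimeter), classifies stressed versus healthy tissue
    from the hue histogram (near-yellow 0-72 versus near-green 73-180),
    registers near-infrared, thermal and chlorophyll-fluorescence frames to
    the RGB mask with an affine control-point fit, and derives water-content,
    canopy-temperature and Fv/Fm photosynthesis metrics. Pot-weight time
    series with irrigation events yield water-use efficiency, plant water
    loss rate and transpiration rate. A deterministic synthetic generator
    renders stress-graded plant scenes and weighing series so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
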