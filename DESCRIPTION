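Package: texdepth
Title: Relative Depth and Surface Sketches from Single Textured Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a relative 3D depth map, a 2D boundary sketch and local
    surface slant/tilt estimates from a single monocular grayscale image of a
    textured surface. The estimator is a hierarchically organised cascade of
    model cortical areas (V1, V2, V4, IT): quadrature Gabor texture-energy
    decomposition, long-range bipole grouping with divisive normalization and
    modulatory feedback, orientation-contrast sketch extraction, and directed
    integration of texture-energy gradients into a globally ordered relative
    depth field. Includes a synthetic-scene generator (textured height fields
    under orthographic or perspective projection with exact ground-truth
    depth) and evaluation utilities (relative error, profile comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    graphics,
    grDevices,
    utils,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    EBImage
Config/testthat/edition: 3
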