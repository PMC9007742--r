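Package: opmtools
Title: Image Processing for Oblique-Plane Light-Sheet Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Processing chain for single-objective oblique-plane light-sheet
    microscopes: deskewing of oblique camera stacks to coverslip-aligned
    volumes, synthesis of bead phantoms and dual-view scenes with
    illumination-path attenuation, point-spread-function characterization by
    tilted-axis Gaussian fitting, large-scale background removal and
    light-sheet illumination correction, iterative multi-scale chunked warp
    registration by phase correlation, content-aware dual-view fusion with a
    Sobel-gradient blend map, L1-robust temporal drift stabilization, and a
    timing simulator for light-sheet stabilized stage scanning.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
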