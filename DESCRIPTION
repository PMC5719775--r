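Package: mrdistort
Title: Grid-Phantom Mapping and Correction of MR System Distortion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Maps and corrects three-dimensional system-related geometric
    distortion in magnetic resonance images using a grid-sheet phantom.
    Provides a synthetic phantom/scanner simulator with known ground-truth
    distortion, adaptive sub-voxel control-point extraction (unsharp masking,
    per-slice adaptive thresholding, directional line-intersection masking,
    watershed separation), CT-to-MR point-set registration with
    polynomial-fit artifact cleaning, forward/reverse read-gradient averaging
    to remove B0 effects, first-order and iterative estimation of the 3D
    displacement field from three orthogonal acquisitions, spline
    interpolation of distortion maps, image rectification, and residual
    validation by re-running the pipeline on corrected volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
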