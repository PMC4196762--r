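Package: negseg
Title: Subvoxel Surface Segmentation by Non-Euclidean Graph Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Globally optimal segmentation of terrain-like surfaces in 3D
    volumetric images (e.g. retinal OCT layers, vessel walls in MR) by the
    minimum closed set / maximum flow formulation, extended to subvoxel
    accuracy by deforming graph node positions with a normalized,
    cost-derived deformation field (non-Euclidean graph search).  Includes a
    synthetic layered-tissue phantom generator with exact partial-volume
    rendering, a bicubic-reconstruction downsampling chain, cylindrical
    unwrapping utilities, and a quantitative evaluation protocol (signed and
    unsigned surface-position and thickness errors, paired t-tests,
    threshold-exceedance fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    png,
    RNifti,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
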