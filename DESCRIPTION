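Package: xsection
Title: Slice-by-Slice Cross-Sectional Geometry of Segmented 3D Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes cross-sectional geometric properties slice-by-slice
    along segmented 3D volumes (micro-CT segmentations and similar image
    stacks): cross-sectional area, centroid, second moment of area about
    principal and user-defined centroidal neutral axes, section modulus,
    polar moment of inertia, maximum Feret diameter, perimeter, mean
    voxel brightness, and compactness. Includes length and material
    normalizations for size-independent comparisons, automatic alignment
    of a segment's long axis with the slicing axis from its moments of
    inertia, Euler-Bernoulli deflection calculators with beam-assumption
    validity checks, readers and writers for NRRD, NIfTI-1 and ordered
    TIFF stacks, a synthetic-shape generator with closed-form ground
    truth for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    tiff,
    EBImage,
    ggplot2,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
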