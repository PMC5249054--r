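Package: mcmorph
Title: 3D Morphometry and Morphology Classification of Breast
    Microcalcifications from Micro-CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the three-dimensional structure of
    breast microcalcifications imaged by micro-computed tomography.
    Reads voxel volumes (TIFF slice stacks or raw plus sidecar header),
    segments calcified objects by global thresholding and 26-connected
    labeling, and computes per-object morphometry: volume, isosurface
    surface area, the surface derivative under simulated thickening, the
    structure model index (SMI; 0 plate-like, 3 rod-like, 4 spherical),
    and sphere/cube equivalent diameters. Per-sample aggregates feed a
    rule-based morphology categorization analogous to mammographic
    BIRADS descriptors (fine linear, fine pleomorphic, coarse
    heterogeneous, not suspicious) and group-level statistics
    (Kruskal-Wallis, Pearson chi-square, Bonferroni correction) across
    histologic B-classification groups. Includes analytic phantom and
    cohort simulators and a packaged 29-sample reference cohort table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
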