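Package: malpaca
Title: Multi-Template Automated Landmarking for 3D Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Automated placement of anatomical landmarks on populations of 3D
    surface meshes using multiple templates. Implements sparse point-cloud
    extraction and closest-point correspondence, feature-based (FPFH + RANSAC)
    and iterative-closest-point rigid alignment, coherent point drift deformable
    registration, single-template landmark transfer (ALPACA), multi-template
    transfer with coordinate-wise median fusion (MALPACA), K-means selection of
    template specimens from a generalized Procrustes / principal component
    morphospace, quantitative evaluation against reference landmarks (RMSE,
    Welch tests, correlation reports, permutation tests over random template
    sets), post-hoc outlier-based quality control of per-template estimates,
    and a synthetic-shape generator with ground-truth landmarks for validation.
    Reads and writes PLY/OBJ/STL/VTK meshes and Slicer FCSV / markups-JSON
    landmark files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
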