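Package: canal3d
Title: Volumetric Measurement of Indirect Spinal Canal Decompression from CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the indirect decompression of the spinal canal and
    neuroforamina after percutaneous cement discoplasty (PCD) from paired
    pre- and postoperative CT scans. Provides Hounsfield-unit segmentation of
    vertebrae and PMMA cement, watertight surface meshing with smoothing and
    uniform remeshing, landmark-based rigid registration of the motion
    segment with Hausdorff-distance quality control, measurement-cylinder
    Boolean volumetry of the free canal volume (the delta-V decompression
    measure), cement wall-thickness mapping, and the accompanying statistical
    battery (Dice similarity, Wilcoxon signed-rank, Spearman correlation,
    two-way absolute-agreement intraclass correlation). A fully synthetic
    motion-segment phantom generator with an independent analytic ground
    truth makes every pipeline stage verifiable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
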