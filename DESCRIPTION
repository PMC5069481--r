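Package: poroct
Title: Bone Morphometry and Intracortical Porosity Analysis for HR-microCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative morphometry of high-resolution microCT
    bone images: trabecular indices (BV/TV, Tb.Th, Tb.Sp, Tb.N) and cortical
    indices (Ct.Th, Ct.OD) from model-independent 3D local thickness,
    volume-class segmentation of intracortical porosity into vascular canals
    and osteocyte lacunae, despeckle sensitivity analysis, a synthetic
    phantom generator with analytic ground truth, a scan-resolution
    simulator for studying partial-volume effects, and the group-comparison
    statistics used in small-n animal studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    png,
    yaml,
    jsonlite,
    withr,
    car,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
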