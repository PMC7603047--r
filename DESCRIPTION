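Package: trabdvc
Title: Digital Volume Correlation and Morphometry for Trabecular Bone
    Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures full-field displacement and strain in trabecular
    bone image volumes under stepwise compression. Implements a global
    grid-based digital volume correlation (DVC) engine with Laplacian
    smoothing, preprocessing of microCT-like 8-bit image stacks
    (filtering, global-threshold segmentation, despeckling, resampling,
    contour masking), standard 3D bone morphometry (BV/TV, Tb.Th, Tb.Sp,
    Tb.N, Conn.D), displacement-to-strain differentiation via hexahedral
    shape functions, the zero-strain / virtual-deformation uncertainty
    framework (systematic and random errors, MAER, SDER, nodal-spacing
    sweeps), load-step strain statistics, and a synthetic generator of
    osteoarthritis-like trabecular microstructures with exactly known
    applied deformations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
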