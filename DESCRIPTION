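Package: uterusSR
Title: Surface-Rendered 3D Models of the Uterus for Fibroid Surgical Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semi-automatic multi-structure segmentation of uterine MR volumes
    by key-slice contour tracing and shape-based inter-slice interpolation,
    surface rendering of the uterine body, endometrium and fibroids via
    marching cubes with Taubin smoothing, fibroid characterization (count,
    size, intramural/subserosal/submucosal type) with a surgical-planning
    report, synthetic pelvic MR phantoms with analytic ground truth, and the
    reader-study concordance and summary-statistic t-test arithmetic used to
    evaluate surface-rendered versus sagittal reading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    Matrix,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
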