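Package: ctmorph
Title: Analytic Morphomics from Single-Slice CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless toolkit for CT body-composition (analytic morphomics)
    measurement. Reads and spatially orders DICOM CT series, reconstructs
    sagittal views for level selection, segments muscle and adipose tissue
    by Hounsfield-unit windowing with manual (threshold brush, eraser) and
    automatic (pseudo-polar abdominal wall detection) methods, computes
    single-slice area and attenuation markers, implements an HTTP plugin
    protocol for external segmentation services with mandatory DICOM
    de-identification, exports masks plus CSV measurements as a ZIP
    archive, and provides Bland-Altman, Spearman, intraclass-correlation
    and ICC-power method-agreement statistics. Includes a parametric
    abdominal CT phantom generator with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    curl,
    httpuv,
    jsonlite,
    png,
    stats,
    utils,
    zip
Suggests:
    callr,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
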