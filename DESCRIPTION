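Package: glyx
Title: Endothelial Glycocalyx Thickness and Microvascular Perfusion from
    Sidestream Dark-Field Videomicroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sidestream dark-field videomicroscopy
    recordings of the microcirculation: vessel centerline detection,
    partitioning into 10 micrometre segments with contrast-based validity
    classification, per-frame red-blood-cell column-width measurement, and
    estimation of the median column width (P50), perfused diameter and
    perfused boundary region (PBR), an indirect measure of endothelial
    glycocalyx thickness.  Includes cohort-level statistics (nonparametric
    tolerance intervals with bootstrap confidence limits, REML variance
    components, covariate screening) and a ground-truthed synthetic scene and
    cohort generator for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    nortest,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
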