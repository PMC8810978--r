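Package: hclquant
Title: Heart/Contralateral Count-Ratio Quantification for Bone-Tracer
    Cardiac Amyloidosis Scintigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative scoring of planar bone-tracer scintigraphy for
    transthyretin cardiac amyloidosis (TTR-CA). Computes the
    heart-to-contralateral (H/CL) count ratio from a circular cardiac
    region of interest mirrored across the sternal midline, applies the
    ASNC three-category rule and single-threshold rules (1.5, 1.3),
    reclassifies equivocal Perugini grade-1 studies through per-grade
    H/CL intervals, and evaluates diagnostic performance (sensitivity,
    specificity, ROC cut-off optimization, Kruskal-Wallis with Dunn
    post-hoc comparisons). Includes a Poisson-noise thorax phantom and a
    synthetic cohort generator so the full pipeline is testable without
    patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'phantom.R'
    'cohort.R'
    'classify.R'
    'io.R'
    'performance.R'
    'stats.R'
    'roi.R'
    'pipeline.R'
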