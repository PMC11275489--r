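Package: drquad
Title: Quadrant Analysis of Diabetic Retinopathy Lesions on a Modified
    ETDRS Grid
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps retinal microaneurysms and hemorrhages onto a modified
    ETDRS grid whose four quadrants extend to the periphery of a 45-degree
    macula-centered fundus photograph, grades diabetic retinopathy with the
    MESSIDOR count-based rule set, and computes per-grade per-quadrant
    cohort statistics (summary tables, one-way ANOVA, pairwise two-sample
    t-tests from raw values or printed summary statistics). Ships a
    table-calibrated synthetic cohort generator (overdispersed
    negative-binomial lesion counts, geometric placement, optional fundus
    renders) and a classical blob detector so the whole pipeline runs
    end-to-end without any image download or trained model weights.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml,
    png
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
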