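Package: foveaseg
Title: Graph-Based Retinal Layer Segmentation and Foveal Morphometry for OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates spectral-domain optical coherence tomography (SD-OCT)
    B-scans of the fovea with known ground truth, segments nine intra-retinal
    boundaries by shortest-path search on gradient-derived weight graphs,
    converts boundaries to magnification-corrected layer thickness profiles
    (Bennett's formula), samples central and 0.5 mm peripheral foveal
    thicknesses in four quadrants, and compares three-group cohorts
    (amblyopic, fellow, control eyes) with ANCOVA adjusted for age and sex,
    Bonferroni-corrected pairwise contrasts, Welch t-tests and Pearson
    correlations. Includes a synthetic cohort generator parameterized by
    published pediatric anisometropic amblyopia group statistics and an
    end-to-end seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff,
    png,
    withr,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
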