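Package: carpofem
Title: Finite-Element Comparison of Fused and Unfused Scaphoid-Centrale Carpal Morphologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale linear-static finite-element pipeline for comparing
    the biomechanical performance of fused versus unfused scaphoid-centrale
    wrist morphologies under knuckle-walking loads. Generates seeded synthetic
    carpal geometries (scaphoid, os centrale, capitate) with labelled articular
    facets in fused and unfused variants, assembles multi-body linear-elastic
    models with cortical and cartilage membrane layers, ligament and foundation
    springs, non-separation sliding contact and distal fixation, solves them
    with sparse direct factorisation, and summarises von Mises stress with
    mesh-weighted statistics (MWAM, MWM) compared across variants by
    Shapiro-Wilk normality checks and Welch two-sample t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
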