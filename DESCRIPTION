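Package: mpusliver
Title: Multiparametric Ultrasound Characterization of Fatty Liver
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for multiparametric ultrasound (mpUS) assessment of hepatic
    steatosis. Implements H-scan tissue characterization with Gaussian-weighted
    Hermite matched filters, shear wave speed and attenuation estimation by
    two-dimensional Fourier (f-k) analysis of tracked tissue displacements,
    contrast-enhanced ultrasound time-intensity curve parameterization with
    vena-cava normalization, histology fat-fraction scoring, and cohort
    classification with Z-scoring, PCA feature contributions and a
    Gaussian-kernel support vector machine. Ships synthetic-data generators
    with known ground truth for every input type so each analysis stage can be
    validated by parameter recovery, plus an end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    quadprog,
    stats,
    utils,
    withr
Suggests:
    png,
    rhdf5,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
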