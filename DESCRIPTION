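Package: torimetry
Title: Toric Intraocular Lens Power Evaluation with Dioptric Power Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates toric intraocular lens (IOL) power calculation across
    corneal keratometry sources (standard keratometry, total keratometry and
    total corneal refractive power). Sphero-cylindrical powers are represented
    as symmetric 2x2 dioptric power matrices, residual postoperative refraction
    is computed by astigmatic vergence propagation through a pseudophakic eye
    model, and outcomes are analysed with prediction-error summaries,
    double-angle astigmatism vector analysis (centroids, surgically induced
    astigmatism, confidence ellipses), one-way ANOVA with Tukey follow-up,
    Cochran's Q tests and noncentral-F power analysis. A seeded synthetic
    cohort generator emulates the statistical structure of a clinical toric
    IOL cohort so the full pipeline runs end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
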