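Package: echometrics
Title: Bilateral-Filter Ultrasound Denoising and Echocardiographic Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Edge-preserving denoising of two-dimensional grayscale
    ultrasound images with a neighborhood-limited bilateral filter and a
    plain Gaussian filter, plus the tooling needed to evaluate the filters
    and the downstream cardiology pipeline without patient data: a
    piecewise-constant cardiac phantom generator with multiplicative speckle
    noise, full-reference image quality metrics (MSE, PSNR, Laplacian edge
    preservation index), derived echocardiographic and electrocardiographic
    quantities (left ventricular ejection fraction, biplane Simpson method
    of discs volume, mean diastolic filling rate from volume-time curves,
    E/A and E/E' ratios, QT dispersion, P-wave terminal force in V1), a
    summary-statistics statistical layer (t-test, one-way ANOVA with LSD
    pairwise comparisons, chi-square, Pearson correlation) that operates on
    printed mean/SD/n triples, and a Gaussian-copula cohort simulator with a
    target correlation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
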