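Package: imbiomark
Title: Non-Invasive Vascular Elastography and Imaging-Based Stiffness Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Windowed affine speckle tracking for radio-frequency (RF) and
    B-mode ultrasound sequences of arteries, assembly of axial-strain
    elastograms, and extraction of cyclic stiffness biomarkers (peak and mean
    systolic/diastolic strain) with the associated pooling schemes and group
    statistics (one-way ANOVA, Kruskal-Wallis, Tukey HSD, Monte-Carlo
    Dunnett). Includes a synthetic pulsating-vessel speckle phantom with
    analytic ground-truth strain, rigid pre-registration for bulk cardiac
    motion, and simple text-friendly containers for sequences, masks and
    result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    tiff
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
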