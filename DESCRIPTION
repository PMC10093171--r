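Package: osteopose
Title: Locomotor Mode and Limb Posture Inference from Femoral
    Cross-Section Microanatomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures compactness and geometric parameters on binary
    mid-diaphyseal bone cross-section images (global and radial sigmoid
    compactness profiles, second moments of area, polar section modulus,
    slenderness ratio), and couples them to phylogenetic comparative
    machinery: phylogenetic flexible discriminant analysis with
    Pagel-lambda optimisation, exhaustive variable-subset selection by
    leave-one-out cross-validation across populations of time-calibrated
    trees, categorical inference for fossil taxa, simulation-based
    phylogenetic ANOVA, Pagel-lambda and entropy-based (delta) signal
    statistics, and phylogenetic generalised least squares. Ships
    parametric generators for annular bone sections and class-structured
    trait datasets evolved on trees so the whole pipeline is testable
    from first principles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phytools,
    MASS,
    png,
    tiff,
    yaml,
    emmeans,
    car,
    Rcpp,
    stats,
    utils,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite
Config/testthat/edition: 3
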