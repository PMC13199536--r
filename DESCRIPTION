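Package: vertebraFE
Title: Subject-Specific Finite-Element Modelling of Vertebrae from QCT with
    Reproducibility Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and exercising CT-based subject-specific
    finite-element (FE) models of metastatic and control vertebrae, and for
    quantifying how operator-dependent segmentation variability propagates to
    mechanical predictions. Includes a synthetic-data module (vertebra
    phantoms with lytic lesions, QCT rendering with a five-rod calibration
    phantom, simulated operator segmentations), densitometric calibration
    from in-line phantom rods, 3D segmentation agreement metrics (relative
    volume difference, Dice, mean surface distance, Hausdorff distance),
    density-driven elasto-plastic material mapping, a quadratic-tetrahedral
    FE solver for displacement-controlled compression with von Mises
    plasticity and isotropic hardening, mechanical outcome metrics, local
    spherical strain probes, and intra-/inter-operator precision statistics
    (coefficient of variation, precision error, absolute relative
    difference, paired tests, exploratory regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    RNifti,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
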