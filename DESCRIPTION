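Package: replanar
Title: Reprojected Planar Scintigraphy Simulation and Agreement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for verifying reprojected planar
    scintigraphy against conventional planar scintigraphy in bone-tracer
    cardiac amyloidosis imaging. Generates seeded digital thorax phantoms
    with known myocardial-to-rib uptake ratios, simulates attenuated
    anterior planar and multi-angle parallel-beam SPECT acquisitions with
    Poisson counting noise, reconstructs with MLEM/OSEM and block
    sequential regularized EM (BSREM) using the relative difference prior,
    synthesizes virtual anterior planar images by attenuation-weighted
    forward projection of the reconstructed volume, computes
    heart-to-contralateral (H/CL) ratios with circular regions of interest
    and the 1.5 positivity cutoff, and quantifies agreement between the
    two imaging pathways with percent agreement, Cohen's and Fleiss's
    kappa (bootstrap confidence intervals), linear regression, and
    Bland-Altman analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    knitr,
    rmarkdown
LinkingTo: Rcpp
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
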