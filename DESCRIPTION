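Package: aortaseg
Title: Cascaded Attention U-Net Segmentation and Morphometry of the Aorta in CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated segmentation of the aortic lumen and wall structure /
    intraluminal thrombus from contrast-enhanced and non-contrast CT volumes,
    built around a cascaded region-of-interest detection stage and an
    attention-gated 3D U-Net trained with a soft Dice loss. Includes a
    synthetic aneurysmal-aorta phantom generator with analytic ground truth,
    divergence-transform and random affine data augmentation, NIfTI
    input/output with isotropic resampling, centerline extraction by
    distance-ordered homotopic thinning, and a morphometry layer (axial and
    centerline-orthogonal diameters, areas, volumes, diameter profiles,
    straightened views) with Bland-Altman, intraclass-correlation and related
    agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    igraph,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
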