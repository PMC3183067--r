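Package: tubediff
Title: Diffusion and Geometry Analysis for Single-Particle Tracking on
    Tubular Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying and correcting the geometric bias that
    tubular membrane curvature introduces into single-particle-tracking
    (SPT) diffusion measurements. Provides a seeded Monte Carlo engine that
    generates matched planar, cylindrical and projected trajectories;
    mean-squared-displacement (MSD) analysis with 1D, 2D and 3D-coordinate
    variants and longitudinal/transversal decomposition; a dimensionless
    bias parameter with simulation-derived correction curves;
    sub-diffraction tube-diameter estimators from transverse localization
    distributions, transversal MSD plateaus, envelope widths and membrane
    mechanics; and astigmatism-based z-calibration for 3D SPT.
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
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
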