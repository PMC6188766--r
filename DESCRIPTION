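Package: bnctsens
Title: Positioning-Error Sensitivity Analysis for Boron Neutron Capture Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale dosimetric sensitivity analysis for single-field
    epithermal-beam boron neutron capture therapy (BNCT) of brain tumors.
    Builds synthetic cylindrical and head voxel phantoms with regions of
    interest, computes four-component physical dose-rate grids with a
    calibrated parametric beam kernel (an explicit stand-in for Monte Carlo
    transport), converts them to biologically weighted Gray-equivalent dose
    using DRSF/RBE/CBE factors and a tumor-to-normal boron concentration
    ratio, normalizes plans to a tumor-coverage prescription, applies rigid
    positioning perturbations (lateral and outward shifts, rotation, tilt)
    with nearest-neighbor resampling, and reports dose-volume histograms,
    ROI dose metrics, percent changes and t-tests across the perturbation
    battery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
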