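Package: dxblink
Title: Diffracted X-Ray Blinking Analysis of Time-Resolved Diffraction Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-pixel intensity autocorrelation analysis of time-resolved
    X-ray diffraction image stacks (diffracted X-ray blinking, DXB).
    Computes the normalized autocorrelation function of each detector
    pixel's photon-count time series, fits a constrained single-exponential
    model with acceptance criteria, aggregates decay constants with
    Cauchy-Lorentz and boxplot statistics, and converts the median decay
    constant into a picometer-scale rotational diffusion coefficient via
    the Bragg geometry of the Debye-Scherrer ring. Includes a synthetic
    blinking-movie simulator (two-state telegraph or angular-diffusion
    kinetics with Poisson photon noise) that provides ground truth for
    every analysis stage, pixel binning, linear detrending, ring-ROI
    selection, frame-splitting robustness analysis, and a command-line
    front end for simulate/analyze/compare runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    tiff,
    png,
    yaml,
    jsonlite,
    minpack.lm,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
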