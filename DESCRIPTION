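Package: qsaMSI
Title: Standard-Addition Quantification for Liquid-Extraction Mass
    Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative mass spectrometry imaging (Q-MSI) by standard
    addition for line-scan liquid-extraction acquisitions such as
    pneumatically assisted nano-DESI. Centroided mzML line scans acquired
    with alternating standard-doped solvents are aligned at ppm tolerance,
    TIC-normalized, and assembled into a data cube; a sliding reading
    frame of block-averaged pixels fits per-pixel standard-addition
    regressions whose x-intercept magnitude is the detected concentration,
    with extrapolation uncertainty propagated from the slope and intercept.
    Internal-standard (one-point) and external-calibration comparators,
    touchdown (spot) quantification, region-of-interest statistics, and a
    synthetic line-scan simulator with known ground truth (concentration
    maps, ion-suppression field, noise model) are included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
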