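Package: sersquant
Title: Statistical Quantification of Spatially Resolved SERS Spectral Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying analytes from spatially resolved
    surface-enhanced Raman (SERS) spectral maps acquired over dried
    sample wells. Every spectrum in a raster-scanned map receives a
    figure-of-merit quality index (baseline-subtracted mean peak
    intensity); calibration curves against log concentration are then
    built three ways: averaging the total spectral population,
    averaging only the highest quality-index spectra, or summing
    pointwise differences between fitted empirical cumulative
    distribution functions of the quality index (the CDF method).
    Includes a synthetic plate generator emulating heterogeneous
    hotspot statistics (sparse exponential analyte amplitudes over a
    congested plasma-like background), replicate aggregation with
    RSD and signal-to-noise comparison tables, and limit-of-quantification
    confirmation by principal component analysis with 95% confidence
    ellipses after IarPLS baseline correction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
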