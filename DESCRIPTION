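Package: dlgcal
Title: Dosimetric Leaf Gap Determination for Rounded Leaf-End MLC Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the dosimetric leaf gap (DLG) of rounded leaf-end
    multileaf collimator (MLC) systems from sweeping-gap ionization chamber
    readings and from radiochromic film measurements of static slit fields.
    Implements the sweeping-gap transmission correction under both the
    nominal-gap and the cross-field dose width conventions with linear
    extrapolation to the gap-axis intercept, a full EBT3-style film chain
    (red-channel net optical density, third-order netOD-to-dose calibration,
    profile extraction, background-tail matching, cross-field width and
    integral dose), and a parametric rounded leaf-tip simulator that
    generates slit-field profiles, sweep readings, transmission readings and
    synthetic film scans with a known ground-truth dosimetric gap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
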