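Package: scanstab
Title: Scan-Number Optimization for FTIR Spectroscopy via the Moment Distance Index
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for choosing the number of interferometer scans to average when
    acquiring FTIR spectra, built around the moment distance index (MDI) and its
    min-max standardized form (SMDI) as a replicate-stability statistic. Provides
    readers and writers for wide-format spectral tables and simple JCAMP-DX files,
    a synthetic generator of soil-like mid-infrared acquisitions with a 1/sqrt(N)
    scan-averaging noise law and linked soil properties, per-setting SMDI spread
    and funnel-convergence analysis with a sustained-threshold recommendation of
    the minimum scan number, and PLS1 regression with leave-one-out cross-validation
    to quantify how the scan setting affects prediction of soil pH, total organic
    carbon, total nitrogen, cation exchange capacity and Olsen phosphorus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
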