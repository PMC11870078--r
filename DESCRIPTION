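Package: breathvar
Title: Dispersion of Breath-by-Breath Parameters During Exercise Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the dispersion of breath-by-breath parameters (tidal
    volume, breathing frequency) around their exercise trend during
    cardiopulmonary exercise testing. Implements the moving standard
    deviation (MSD_n) and the standard deviation of residuals from local
    degree-2 polynomial regression (LOESS) at configurable spans, a
    synthetic breath-series generator with exercise trends and sighs, a
    Monte-Carlo bias/precision study of the estimators, and per-phase
    LOESS fitting for real multi-phase tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    withr,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
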