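Package: raschcat
Title: Rating-Scale Rasch Calibration and Computerized Adaptive Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for polytomous Rasch measurement of survey instruments and
    for running computerized adaptive tests (CAT) over a calibrated item bank.
    Implements the rating-scale model (one shared set of step calibrations for
    all items), Newton-Raphson person-measure estimation, joint maximum
    likelihood item calibration with infit/outfit misfit screening,
    person-separation reliability and the SEM-based CAT stopping rule,
    principal-component diagnostics of standardized residuals for
    unidimensionality, rating-category quality checks, model-based response
    simulation, and item-by-item group comparisons (Welch t-tests and
    chi-square tables). Ships a calibrated job-satisfaction item bank as a
    worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
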