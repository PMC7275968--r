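Package: quadspec
Title: Quantification of Severely Overlapped Four-Component UV-Vis Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Univariate and multivariate quantification of four co-formulated
    drugs (atenolol, paracetamol, hydrochlorothiazide, levofloxacin) from
    severely overlapped UV-Vis absorption spectra, with an optional urine
    background. Implements the extended derivative ratio (EDR) method
    (ternary-mixture divisors, Savitzky-Golay derivatives of ratio spectra,
    amplitude calibration) and multivariate curve resolution by alternating
    least squares (MCR-ALS) with SIMPLISMA initialisation, non-negativity and
    correlation constraints. Includes the five-level four-factor calibration
    design, ICH-style validation statistics (LOD/LOQ, recovery, RSD, t/F
    comparison, prediction figures of merit), urinary-excretion arithmetic,
    greenness assessment (NEMI profile, Analytical Eco-Scale), and a seeded
    synthetic-spectra generator used in place of instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
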