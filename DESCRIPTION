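Package: ramandx
Title: Raman Spectral Preprocessing, Differential Band Statistics, and
    Penalized Logistic Tissue Classification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discriminating tumor from normal tissue with Raman
    microspectroscopy. Provides plain-text spectrum I/O, a synthetic
    vibrational-spectrum generator with pseudo-Voigt bands and grouped
    (per-cell / per-mouse) amplitude heterogeneity, a preprocessing chain
    (cosmic-ray despiking, baseline subtraction, phenylalanine-band
    normalization, fingerprint-region cropping, standardization),
    per-wavenumber two-sample t statistics with a permutation-based false
    discovery rate, L2-penalized logistic regression with leave-one-out
    penalty selection nested inside leave-group-out cross-validation, PCA
    cluster ellipsoids, and band-intensity chemical imaging of mapped
    acquisitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
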