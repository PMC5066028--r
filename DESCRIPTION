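Package: sutccsp
Title: Strong Uncorrelating Transform Complex Common Spatial Patterns for
    Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Signal", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for two-class motor-imagery EEG analysis built around
    complex-valued common spatial patterns. Extracts mu (8-13 Hz) and beta
    (13-25 Hz) rhythms with noise-assisted multivariate empirical mode
    decomposition (MEMD), forms complex trials z = mu + j*beta, and fits
    three spatial-filter variants: classical CSP, complex CSP using the
    covariance only (CCSP), and SUTCCSP, which additionally diagonalizes the
    pseudocovariance through the strong uncorrelating transform obtained by
    Takagi factorization. Includes a synthetic EEG generator with known
    lateralized ground truth, a repeated stratified cross-validation harness
    with a binomial significant-subject criterion, hemispheric power-difference
    asymmetry analysis over symmetric electrode pairs, a minimal EDF/EDF+
    reader, and a command-line interface driving the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
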