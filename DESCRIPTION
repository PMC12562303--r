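Package: ordspec
Title: Ordinal Spectrum Analysis of Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Frequency-domain characterization of the ordinal-pattern
    (Bandt-Pompe) symbolic dynamics of a univariate time series.  The
    symbol sequence is treated as an integer-coded Markov chain; its rank
    autocovariance is transformed into an "ordinal spectrum", and
    significance against the null hypothesis of a (possibly monotonically
    transformed) linear stochastic process is assessed with IAAFT
    surrogate data, per-frequency z-tests and Benjamini-Hochberg false
    discovery rate control.  Includes generators for the synthetic
    benchmark systems (logistic map, Roessler attractor, Gaussian and
    power-law noise, nonlinear non-Gaussian stochastic models) and a
    small command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
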