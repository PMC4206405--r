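Package: mwmar
Title: Moving-Window Multivariate Autoregressive Models for Community Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits first-order multivariate autoregressive (MAR(1)) models to
    multispecies abundance time series by conditional least squares, and
    re-fits them over overlapping moving windows to detect time-varying
    species interactions, environmental effects, and community stability
    (the dominant eigenvalue of the interaction matrix). Includes parametric
    bootstrap confidence intervals for all coefficients, residual diagnostics
    (Shapiro-Wilk normality scans with Bonferroni correction, residual-data
    correlation screening, QQ exports), preprocessing of raw plankton
    monitoring records into monthly log-abundance and climatology/anomaly
    covariate panels, and seeded simulation tools (stationary and
    regime-shifting generators, a Lake-Washington-like synthetic community,
    window-size accuracy and transition-bias experiments).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
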