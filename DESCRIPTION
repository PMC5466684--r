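Package: stproj
Title: Space-Time Projection Kriging for Disease Incidence Mapping
Version: 0.1.0
Authors@R:
    person("stproj", "developers", email = "stproj@example.org", role = c("aut", "cre"))
Description: Tools for mapping yearly, point-referenced disease incidence with
    the space-time projection (STP) technique and a reference spatiotemporal
    ordinary kriging (STOK) implementation. STP models incidence as a traveling
    (frozen) random field, compresses the time axis into space through the
    coordinate transform s_hat = s - v*t, performs ordinary kriging in the
    reduced two-dimensional domain with an exponential covariance of the
    projected lag, and back-transforms the estimates to space-time. The package
    includes indirect age standardization, log(x+1) normalization,
    moving-window detrending, empirical space-time covariance estimation with
    AIC-based model fitting, the spread-velocity solver linking the separable
    space-time covariance to its projected form, k-fold cross-validation with
    ME/MAE/RMSE summaries, a seeded traveling-random-field simulator for
    verification, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
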