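Package: lueflux
Title: Environmental Controls on the Light Use Efficiency of Gross
    Primary Production
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the light use efficiency (LUE) of gross primary
    production from daily eddy-covariance flux records and models its
    environmental controls.  Provides FLUXNET-style preprocessing
    (cloudiness index, Bristow diffuse-transmittance gap-filling,
    smoothing-spline interpolation of sparse fAPAR, quality and
    growing-season filters, 15-day compositing), gamma generalized
    linear mixed models of LUE with year-within-site random intercepts
    including model selection, variance partitioning, conditional
    response curves and leave-one-site-out cross-validation, an
    optimality-based LUE simulator (P-model) for mechanistic
    comparison, benchmarking utilities for third-party model output
    (Beer-Lambert fAPAR from LAI, Nash-Sutcliffe efficiency), and a
    synthetic multi-site data generator with known ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
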