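Package: acclimtol
Title: Acclimated Tolerance Surfaces for Experimental Evolution in
    Fluctuating Salinity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing the evolution of environmental tolerance in
    microbial experimental evolution under autocorrelated (AR1) salinity
    regimes. Simulates stochastic salinity series and serial-transfer
    logistics, jointly fits bivariate acclimation-by-assay tolerance surfaces
    by maximum likelihood under negative-binomial live-count and beta-binomial
    dead-count observation models, regresses surface parameters on realized
    environmental moments (mean, variance, autocorrelation, predictability)
    with likelihood-ratio and Wald inference, and analyzes per-cell glycerol
    plasticity with delta-method error propagation and multiple-imputation
    (Rubin / D1) pooling. Includes a synthetic-data generator reproducing the
    full cross-salinity assay design for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    TMB,
    glmmTMB,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    withr
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
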