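Package: nctr
Title: Network Control Energy of Transitions Between Cortical Activation States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear network control theory over weighted structural
    connectomes: finite-horizon optimal control energy between regional
    activation maps (via the state-costate two-point boundary-value problem),
    all-pairs transition-energy matrices and their asymmetry and variability
    statistics, degree- and geometry-preserving rewiring nulls, spherical
    rotation ("spin") surrogates for parcellated cortical maps, heterogeneous
    control-input weightings derived from receptor-density and disease
    cortical-abnormality maps, effective-resistance network variance, partial
    rank correlations and dominance analysis of transition-cost predictors,
    and a synthetic-data generator producing geometric connectomes and
    spatially autocorrelated maps for fully reproducible desk-scale runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
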