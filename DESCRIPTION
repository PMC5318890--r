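Package: lakexergy
Title: Thermodynamic Ecosystem-Health Indicators and Boosted Regression
    Trees for Lake Plankton Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes eco-exergy and specific eco-exergy of a lake plankton
    community from wet-weight biomass monitoring data, resolves left-censored
    (below limit-of-detection) water-quality records by a three-tier
    drop / half-LOD / truncated-normal-imputation policy, screens collinear
    predictors by Pearson correlation, explains the indicators with a
    from-scratch gradient-boosted regression-tree model (Gaussian loss,
    cross-validated iteration selection, relative influence, one- and
    two-variable partial dependence), judges model adequacy by Nash-Sutcliffe
    efficiency, RSR and percent bias, and maps station values by
    inverse-distance-weighted interpolation. A seeded synthetic survey
    generator emulating a 33-station by 12-month shallow-lake campaign makes
    every stage testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    mgcv,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
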