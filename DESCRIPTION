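Package: foresthurdle
Title: Hurdle Mixed Models of Land-Use Impacts on Tropical Forest Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested workflow for synthetic modelling of how land use,
    forest cover, human population density and vegetation offtake (iNDVI)
    affect the occurrence and abundance of individual species in tropical
    and sub-tropical forests.  Includes a multi-study synthetic data
    generator with known ground truth, an integrated-NDVI vegetation
    offtake metric with quality filtering and spike screening, effort
    correction and occurrence derivation for long-format abundance
    records, area-of-occupancy range classification, two-stage hurdle
    mixed models (binomial occurrence GLMM and Gaussian LMM on log
    abundance) with marginality-respecting backward selection and
    R-squared for mixed models, residual diagnostics (Pagel's lambda on a
    Grafen-calibrated taxonomy tree, per-study Moran's I with a binomial
    meta-test), and derived community-level summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    glmmTMB,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
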