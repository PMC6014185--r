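Package: podomap
Title: Environmental Suitability and Geostatistical Burden Mapping for Podoconiosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for mapping podoconiosis (non-filarial
    elephantiasis) from community prevalence surveys and gridded environmental
    covariates. Stage one fits an ensemble of boosted regression trees and
    random forests to presence/background data, with a kernel-density sampling
    bias surface, weighted pseudo-absences and repeated split evaluation
    (AUC, TSS, PCC), producing a mean suitability surface, confidence bounds
    and a thresholded binary limits map. Stage two fits a binomial logistic
    geostatistical model with an exponential-covariance spatial random effect
    and a community-level nugget, predicts prevalence with uncertainty inside
    the environmental limits, computes exceedance probabilities against a
    policy threshold, and validates the spatial structure with a Monte-Carlo
    variogram envelope. Downstream burden arithmetic converts prevalence and
    adult population surfaces into population at risk and case counts
    aggregated over administrative polygons. A synthetic-world generator
    (spatially correlated covariate fields, a known truth surface, clustered
    surveys with binomial counts) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma,
    ranger,
    xgboost
Suggests:
    glmmTMB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
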