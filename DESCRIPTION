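Package: nhpikit
Title: Natal Habitat Preference Induction from Step-Selection Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies natal habitat preference induction (NHPI) from animal
    tracking data and habitat rasters. Characterizes natal territories by
    buffer composition, fits a scaled principal component analysis shared by
    natal sites and step end-locations, clusters natal habitats by
    furthest-neighbour agglomeration, builds matched used/available step
    designs with exponential step lengths and uniform turning angles, fits
    per-individual-year conditional logistic regressions by Newton iteration,
    and summarizes inter- and intra-individual variation in the resulting
    selection coefficients with six variation metrics whose uncertainty is
    propagated by coefficient simulation. A synthetic-data module generates
    landscapes, nests and hourly trajectories under a known step-selection
    process so that the whole pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    multcomp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
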