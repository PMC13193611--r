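Package: budcall
Title: Division-Event Detection and Replicative Lifespan Quantification
    for Single-Cell Yeast Aging Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage framework for detecting budding (cell-division)
    events in phase-contrast time-lapse crops of trapped yeast mother cells
    and quantifying replicative lifespan. Stage one pretrains a masked
    auto-encoder vision transformer on unlabeled single-cell crops; stage
    two embeds 11-frame temporal windows with the pretrained encoder and
    classifies the center frame as budding or non-budding with a lightweight
    temporal transformer. Includes frame-probability post-processing into
    discrete division timelines, Hungarian event matching with
    tolerance-window precision/recall/F1, lifespan agreement statistics,
    smoothed cell-cycle trajectories, and a synthetic mother-machine movie
    generator with known division schedules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    Rcpp,
    signal,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
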