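Package: nichemax
Title: Presence-Only Maximum-Entropy Niche Modelling with Null-Model,
    Boyce and Jackknife Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits maximum-entropy habitat-suitability models to
    presence-only species occurrences over aligned environmental raster
    stacks, with the feature expansion, regularization and logistic
    output scale of the classic maxent defaults.  Models are validated
    with presence-background AUC, a random-occurrence null model, the
    continuous Boyce index, and a small-sample leave-one-out jackknife.
    Suitability maps are binarized at the minimum-training-presence
    threshold and compared pairwise between species with Schoener's D,
    the Hellinger-based I statistic and a range-overlap index.  A
    synthetic-landscape generator (spatially autocorrelated gradients,
    categorical land cover, derived slope and distance layers, and
    presence samples drawn from known species response curves) supports
    end-to-end testing and parameter-recovery studies without external
    geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
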