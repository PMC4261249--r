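Package: dpcrsim
Title: Variance-Component Simulation and Design Analytics for Digital PCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Poisson-based absolute quantification for digital PCR
    (dPCR) partition counts, with uncertainty estimates that remain
    valid under realistic technical variation.  Provides single-sample,
    pooled and replicate-based concentration estimators with asymptotic
    and empirical confidence intervals; a stochastic simulator of the
    full dPCR data-generating process with independently switchable
    variance components (pipette error, unequal partition size, random
    partition loss, endpoint misclassification, fluorescence
    thresholding); closed-form design analytics (optimal dilution,
    replicate-number planning, partition-loss precision penalty,
    misclassification and partition-size bias, volume-calibration
    bias); and a Monte-Carlo scenario engine for coverage, bias and
    RMSE studies over concentration grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
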