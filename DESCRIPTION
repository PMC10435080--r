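Package: whiskerVT
Title: Wake Sensing with Seal Whisker Arrays and an Interpretable Video Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates how an array of seal whiskers senses the wake of an
    upstream circular plate, and trains an interpretable factorized
    spatio-temporal transformer to recover the plate's location and
    orientation from root bending-moment signals. The package provides a
    parametric undulated-whisker array model, a kinematic vortex-ring wake
    generator (alternating shedding, tilt-induced inclination and strength
    asymmetry, a steady two-leg regime at extreme tilt), a quasi-static
    drag-lift load model reducing segment forces to body-fixed root
    moments, DC/AC signal decomposition onto a 9x22 sensing grid, and a
    from-scratch video transformer with tubelet embedding, factorized
    spatial/temporal self-attention, Adam training, and attention-rollout
    temporal/spatial importance maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
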