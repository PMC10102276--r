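Package: lgcpfuse
Title: Integrated Point Process Models for Presence-Only Species Distribution Data
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits integrated log-Gaussian Cox process models that fuse
    structured presence records (e.g. nest locations) with opportunistic,
    effort-biased sightings (e.g. citizen-science checklists) through a
    shared latent intensity and a thinned observation process. Provides
    covariate engineering for gridded environmental layers (moving-window
    scale summaries, distance transforms, water/vegetation composites),
    downweighted Poisson quadrature regression with LASSO variable and
    scale selection, a lattice Gaussian Markov random field approximation
    to the Matern SPDE spatial field with AR1 year-to-year persistence,
    MAP-plus-Laplace inference, annual intensity prediction with SEDI
    suitability thresholding and bootstrap abundance indices, and
    spatial/temporal block cross-validation for transferability
    assessment. A seeded synthetic-landscape simulator makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
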