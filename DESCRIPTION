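Package: eidolonvis
Title: Visibility of Eidolon Image Distortions from Image Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how visible Eidolon-style image distortions
    are to human observers, and how well image-computable statistics predict
    that visibility. Generates Eidolon distortions (pixel disarray along a
    smoothed Gaussian random vector field controlled by reach and grain),
    computes contrast-energy and spatial-coherence statistics with a linear
    scene-versus-texture classifier, evaluates a battery of image-difference
    metrics including steerable-pyramid texture statistics, fits hierarchical
    Bayesian Weibull psychometric models and per-metric probit regressions to
    odd-one-out trial data via MCMC, and ranks metrics against the
    experiment-based oracle model by WAIC/ELPD. Includes synthetic scene and
    texture image generators and simulated observers so the full analysis can
    be exercised without behavioral data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    e1071,
    png,
    rjags,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
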