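Package: egoallo
Title: Egocentric and Allocentric Spatial Coding Analysis for Multi-Port
    Orienting Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for dissociating self-centered (movement
    direction) from world-centered (port position) coding in frontal cortical
    populations recorded during a visually guided multi-directional orienting
    task on a seven-port hexagonal wall. Provides the task geometry and
    session designs, a synthetic Poisson spike-train generator with known
    spatial tuning, single-neuron Poisson GLM selectivity with cross-validated
    likelihood permutation tests, tuning-geometry descriptions (preferred
    direction and position, start-target tuning correlation, encoding switch
    times), gain-field versus additive encoding-model comparison by
    cross-validated Poisson maximum likelihood, pseudopopulation decoding of
    2D spatial variables via PCA and multivariate regression, and
    reference-frame recurrent-network simulations compared to neural
    populations with representational similarity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
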