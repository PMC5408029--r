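Package: gravobs
Title: Ideal-Observer Simulation of a Strong Gravity Prior in Interceptive Vision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a Bayesian ideal observer that infers the horizontal
    velocity of a parabolic target approaching head-on, from two noisy optical
    variables: the elevation angle and its rate of change. Optical values are
    encoded as Poisson spike counts across banks of Gaussian tuning curves and
    decoded either by maximum likelihood alone or by combining the likelihood
    with a Gaussian prior over gravitational acceleration. Provides the
    trajectory family, the population encoder/decoder, candidate-trajectory
    readouts, Gaussian prior-likelihood fusion, a seeded trial simulator with
    prior-mean sweeps, configuration handling, and a command-line driver.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
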