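Package: motorlottery
Title: Internal Models of Motor Error in Target-Choice Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether a decision maker carries an accurate
    internal model of her own motor error. Estimates true reach-endpoint
    distributions (bivariate Gaussian standard deviations, anisotropy,
    correlation) from speeded-pointing data; computes hit probabilities of
    rectangular and circular targets under Gaussian and uniform-disk error
    models; simulates two-interval target-choice experiments with transformed
    up-down staircases; fits Quick-Weibull psychometric functions by maximum
    likelihood to recover equivalent radii; inverts equivalent radii to an
    internal Gaussian model (variance and anisotropy) and classifies choosers
    as Gaussian-type or area-matching-type by a nested likelihood-ratio test
    with parametric-bootstrap confidence intervals; and reproduces
    expected-gain and efficiency computations for motor lotteries with
    reward and penalty regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
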