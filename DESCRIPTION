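Package: levyflux
Title: Langevin Modelling of Brain-Network Activity with Alpha-Stable Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models one-dimensional network activity time series (such as
    resting-state BOLD fMRI traces) as a discrete Langevin process with a
    linear relaxation drift and additive alpha-stable noise. Provides
    numerics for the alpha-stable family (characteristic function,
    Chambers-Mallows-Stuck sampling, density and distribution functions by
    characteristic-function inversion), drift recovery from binned
    conditional increments, four-parameter stable fits via regression on
    the empirical characteristic function with quantile initialisation,
    survival-function tail-exponent diagnostics, two-sample
    Kolmogorov-Smirnov and Anderson-Darling goodness-of-fit testing with
    Monte Carlo power assessment, a synthetic multi-subject cohort
    generator with known ground truth, and an end-to-end per-network
    analysis pipeline with JSON/CSV reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
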