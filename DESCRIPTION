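Package: statoddball
Title: Simulation and Analysis of Evoked Responses to Statistical Outliers
    in Stochastic Tone Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse magnetoencephalographic (MEG)
    responses to statistical outliers embedded in stochastic tone streams.
    Generates tone sequences whose log-frequencies follow a Gaussian
    contextual distribution with embedded standard and odd probe tones,
    simulates multichannel sensor recordings with planted auditory and
    mismatch-negativity-like components, and implements the full evoked-field
    analysis chain: zero-phase band-pass filtering, downsampling, epoching and
    baseline correction; spatio-temporal scalp-map volumes with a
    mass-univariate general linear model and sign-flip max-statistic
    permutation inference; a maximum signal-to-noise spatial filter via
    generalized eigendecomposition; and a frequency-local adaptation analysis
    with sampled permutation tests comparing narrow and broad contexts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
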