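Package: spikereliability
Title: Trial-to-Trial Spike-Timing Reliability Analysis for Trial-Structured Auditory Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies auditory neural responses to repeated, trial-structured
    stimulus sequences. Provides normalized response strength (RS) per trial and
    per block, stimulus-specific adaptation rates from early-trial regression,
    and spike-timing reliability (CorrCoef) as the mean pairwise Pearson
    correlation between Gaussian-convolved spike trains, with permutation null
    models, kernel-width sweeps, piecewise-linear time warping of spike trains
    onto a per-syllable reference axis, and within-sequence syllable-pair
    context analysis. Includes a generator of synthetic trial-structured spike
    trains (inhomogeneous Poisson with repetition adaptation and controlled
    duration/timing jitter) emulating playback experiments with identical
    versus naturally varying sequence renditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
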