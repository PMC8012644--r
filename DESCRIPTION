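Package: v4intensity
Title: Single-Trial Analysis of Attentional Intensity in Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for single-trial analysis of spatially nonselective
    attentional intensity in extrastriate visual cortex. Provides a
    synthetic session generator with known ground truth (signal-detection
    observer with direction-dependent exponential reward-state dynamics,
    pupil-linked arousal state, negative-binomial spike counts), behavioral
    signal-detection summaries (d-prime, criterion, block-aligned dynamics,
    exponential fits, hysteresis), pupil-spike coupling analyses,
    rate-based spike statistics (PSTH, mean-matched Fano factor, noise
    correlations, reward-matched counts, PSTH PCA), bivariate-Gaussian
    receptive-field geometry, maximum-likelihood negative-binomial GLM
    encoding models of single-trial spike counts, and Bayesian
    log-likelihood-ratio population decoding of saccade, choice, and
    orientation change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
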