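Package: tempopred
Title: Simulation and Analysis of Temporally Variable Auditory Oddball Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse auditory oddball experiments in
    which the stimulus-onset asynchrony (SOA) between successive sounds is
    drawn from quantized Gaussian distributions of varying temporal
    variability. Provides generators for constrained oddball stimulus
    timelines, a parametric synthetic observer (accuracy, gamma response
    times, rhythmicity ratings, adaptive staircase), trial-history local
    temporal statistics with two-dimensional sliding-window binning,
    one-sample sign-flip cluster-based permutation tests on binned
    performance maps, and a generalized linear mixed-model inference suite
    (likelihood-ratio model comparison, Type II Wald tests, Tukey-adjusted
    pairwise contrasts, local-versus-global variability odds ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    glmmTMB,
    car,
    emmeans,
    jsonlite,
    yaml,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
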