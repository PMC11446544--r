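Package: cardiorivalry
Title: Cardiac-Phase-Locked Stimulation and Analysis for Binocular Rivalry
    Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for experiments that entrain visual stimuli to the cardiac
    cycle. Provides streaming-contract ECG processing (5-15 Hz bandpass,
    Pan-Tompkins R-peak detection, T-wave offset delineation), cardiac-phase
    locked pulse scheduling with analog-to-digital latency compensation,
    cardiac-angle manipulation checks with subject- and group-level
    (random-effects) circular bootstraps, gamma generalized estimating
    equations for binocular-rivalry dominance durations, a Bayesian mixture
    model of heartbeat-discrimination accuracy (at-chance binomial versus
    shifted-Beta above-chance component) with prevalence estimation and
    posterior membership screening, and a synthetic-data generator that
    emulates the statistical structure every stage assumes, so the full
    pipeline is testable without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    grDevices,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
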