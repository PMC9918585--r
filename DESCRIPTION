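Package: esmdesign
Title: Sampling Design and Power Analysis for Experience Sampling Studies
    of Affect Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing experience sampling (ESM) studies of affect
    dynamics. Computes seven person-level affect dynamics measures (trait
    mean, within-person standard deviation, relative standard deviation,
    root mean square of successive differences, Teager-Kaiser energy
    operator, probability of acute change, and lag-1 autocorrelation),
    quantifies how accurately each is estimated under different sampling
    strategies (random, temporally close, temporally distant, specific
    times of day, specific days of the week) via subsample-versus-truth
    RMSE curves with bootstrap confidence intervals, and estimates
    statistical power to detect correlations between affect dynamics
    measures and outcomes over a grid of (participants x observations)
    designs by Monte Carlo simulation. A synthetic ESM data generator with
    known ground-truth dynamics supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
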