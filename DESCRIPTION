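Package: vocchess
Title: Value-of-Computation Analysis of Thinking Time in Clocked Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for asking whether the time players spend thinking tracks
    the value of computation. Maps engine-style position evaluations to a
    win-probability utility, scores each position's benefit of computation
    (the utility gained by playing the deep-search move instead of the
    shallow-search move) and its expectation under Gaussian beliefs centred
    on shallow evaluations, estimates empirical value functions over time
    remaining and position advantage, derives time-cost curves and
    optimal-stopping deliberation budgets from them, and fits move-time
    regressions with AIC-based concavity comparisons. Includes a synthetic
    generator for clocked two-player game data with paired shallow/deep
    evaluations and policy-following players, so the full pipeline runs and
    is testable without any external dataset or engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
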