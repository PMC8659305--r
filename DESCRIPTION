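Package: crowdshift
Title: Simulation and Fitting of Social Information Use in Collective
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how people revise numerical estimates of
    large quantities after seeing estimates from other group members, and
    how restructuring what is shared can counteract the human tendency to
    underestimate large quantities.  Provides a synthetic-experiment
    generator (truncated Laplace log-estimates with a tunable
    underestimation bias), three social-information selection rules
    (random, median, and a bias-compensating shifted-median rule), an
    agent-based model of social information integration with distance,
    asymmetry and similarity effects, estimation routines that recover
    the model parameters from record tables (spike-and-Gaussian mixture
    fits, moving-bin cusp fits, dispersion regressions), and
    question-level bootstrap statistics for collective and individual
    accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
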