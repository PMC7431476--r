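Package: cogmapr
Title: Scoring, Simulation and Analysis of Route-Learning Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for spatial-cognition experiments in which participants
    learn walked routes and their configurational knowledge is assessed with
    direction estimates, distance estimates, sketch maps and pathway-completion
    (path-integration) tasks.  Provides route and training-path geometry,
    Euclidean bidimensional regression (Tobler) for sketch-map scoring, circular
    absolute-error scoring of pointing tasks, a Monte Carlo simulation that
    reconstructs sketch maps from distance-ratio and direction-error
    distributions, split-plot (mixed) ANOVA with partial eta-squared and
    orthogonal polynomial trend contrasts, effect sizes and summary-statistic
    t tests, and a seeded generator of complete synthetic experiments for
    testing the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
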