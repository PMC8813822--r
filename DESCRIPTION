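Package: tdcontagion
Title: Temporal-Discounting Contagion: Grid-Bayesian Estimation and
    Divergence-Based Social Influence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and analyses a five-block Self/Other temporal
    discounting task in which participants learn the delay-discounting
    preferences of simulated agents. Implements hyperbolic subjective
    value with softmax choice, trial-wise Bayesian estimation of
    (log k, log beta) on a discrete grid with block-wise prior carryover
    and resets, a signed Kullback-Leibler divergence measure of
    preference contagion between Self-block posteriors, cohort-level
    exclusion rules, and a group-level statistical battery (robust
    trimmed-mean t-tests, JZS and interval-null Bayes factors,
    equivalence bounds from power analysis). Includes a synthetic-cohort
    generator with tunable ground-truth contagion strength for
    end-to-end validation by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
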