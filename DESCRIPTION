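Package: visuosdt
Title: Signal Detection Analysis of Online Visuo-Perceptual Testing in
    Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy analysis pipeline for case-control online
    visuo-perceptual testing in Parkinson's disease. Scores
    two-alternative forced-choice, hidden-figures, size-matching
    (Ebbinghaus), adaptive-staircase acuity and alternating-tap tasks
    from trial-level records; applies cohort quality-control and
    exclusion rules; estimates per-participant signal detection
    parameters (d-prime and criterion); fits a hierarchical Bayesian
    signal detection model per group by Gibbs sampling with convergence
    diagnostics and posterior group-difference probabilities; and runs
    the classical comparison battery (Welch t, Mann-Whitney, chi-square,
    mixed-design ANOVA, covariate-adjusted regression, Bonferroni
    correction, age-matched trimming). A synthetic-cohort generator with
    the study's task designs supports testing and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    coda,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
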