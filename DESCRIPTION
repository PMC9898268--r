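Package: driftlearn
Title: Quantifying Motor Exploration with Drifting Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for studying exploration during
    motor skill learning from joint-angle recordings. Movement cycles are
    extracted from elbow and knee angle time series, characterised by the
    continuous relative phase (CRP) between the two joints, and clustered
    into coordination patterns with a discriminative (Fisher-EM style)
    Gaussian mixture whose number of components is chosen by a BIC plateau
    rule. The chronological sequence of pattern labels is then modelled with
    order-1 drifting Markov models whose transition matrix drifts
    polynomially along the sequence; the per-pattern distance between a
    degree-1 (linear) and a degree-3 model yields a quantity-of-exploration
    statistic. Exponential learning curves f(t) = a*exp(-b*t) + c are fitted
    to per-session stroke frequency, and a battery of within-subject
    statistics (paired t, Levene, two-way repeated-measures ANOVA with
    sphericity corrections, Bonferroni post-hocs, effect sizes, correlations)
    supports inference. A seeded synthetic-learner generator with known
    search strategies provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
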