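Package: gamespan
Title: Simulation and Psychometric Validation of a Gamified Adaptive
    Auditory Span Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for an adaptive (one-up/one-down staircase) auditory
    short-term memory span game and its psychometric validation. Implements
    the staircase trial flow, the base-plus-partial-credit span score, the
    mean-span rule for fixed-ladder digit span, order-free free-recall
    scoring, rule-based keyword transcription scoring and the extraversion
    composite; a seeded synthetic cohort generator with a common-factor
    cross-task correlation structure; convergent-validity correlation tables
    with Bonferroni correction, two-way random-effects intraclass
    correlation, a Bayes factor for a Pearson correlation under a stretched
    beta prior, and analytic correlation power; grouped-binomial logistic
    mixed models with crossed random intercepts and likelihood-ratio tests;
    and resampling-based power curves over participant subsamples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
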