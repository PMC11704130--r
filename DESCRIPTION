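Package: concreteness
Title: Headline Concreteness Scoring and Clickthrough Moderation Meta-Analysis
Version: 0.1.0
Authors@R: person("Avery", "Collins", email = "avery.collins@example.org",
    role = c("aut", "cre"))
Description: Computes a continuous, lexicon-based concreteness score for news
    headlines (entity tagging, stopword filtering with forward-reference and
    pronoun exceptions, rule-based morphological fallback, averaging) and runs
    the downstream meta-analytic pipeline for headline A/B-test archives:
    decomposition of tests into validly comparable same-image headline sets,
    2-SD standardization, a binomial random-intercepts random-slopes
    multilevel model with a cross-level interaction, simple-slopes tests with
    Holm correction, Johnson-Neyman significance regions, rater-reliability
    statistics (one-way intraclass correlations), and a synthetic experiment
    generator with parameter-recovery and power-analysis harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
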