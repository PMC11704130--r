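---
title: "Headline concreteness and clickthrough moderation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Headline concreteness and clickthrough moderation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Digital publishers A/B-test headlines: several headline--image "packages"
for one article are randomly shown to visitors, and clicks out of
impressions are recorded per package. A long-standing question is whether
"curiosity gap" headlines (vague, information-withholding) or summary
headlines (concrete, information-rich) attract more clicks; experiments
disagree. One resolution is to replace the binary genre label with a
continuous measure of how much perceptible information a headline offers —
its *concreteness* — and to ask whether the effect of a headline's
concreteness on its clickthrough rate (CTR) depends on the concreteness of
the headlines it competes against. This package implements that measurement
and the full meta-analytic machinery around it, plus a synthetic experiment
generator so every stage is testable without the (request-only) experiment
archive.

## The concreteness score

Word-level concreteness norms assign each English word a mean human rating
on a bounded 0--5 scale (e.g. *tomato* 5, *sound* 3.7, *idea* 1.62). A
headline's score is the arithmetic mean over its scoreable components:

1. **Entities.** Person, place, and organization mentions are assigned the
   maximal rating of 5, one component per mention (multi-token names are one
   component).
2. **Stopword filtering with exceptions.** Standard English stopwords are
   removed, *except* forward-reference words (*this*, *these*, *that*,
   *those*) and personal pronouns — function words that headlines use to
   manufacture information gaps. Punctuation and cardinal numbers are
   ignored.
3. **Morphological fallback.** Each remaining token is looked up directly;
   on failure a singular form, then a present-tense form, then a base
   adjective is tried, re-querying the lexicon between steps; a hyphenated
   token that still fails is split and the halves' ratings averaged.
4. **Exclusion.** If any token with three or more letters remains
   unresolved, the headline is excluded (`unmatched_long_word`) rather than
   scored from partial information; unresolved tokens of one or two letters
   are dropped silently. Headlines with no scoreable components at all are
   excluded as `no_scoreable_tokens` — the mean is undefined and we refuse
   to fabricate one.

So `"Kamala Harris Visits Poland"` scores (5 + 3.92 + 5)/3 = 4.64 with a
lexicon in which *visit* is 3.92.

### The entity backend

The reference implementation of this measure uses a statistical named-entity
recognizer. No such model is available in this environment, so
`detect_entities()` ships a deterministic stand-in: a gazetteer matcher over
capitalized tokens (given names, places, organizations), with a
surname-absorption rule — a given name absorbs the following capitalized
token unless that token is a gazetteer entry or resolves as an ordinary
lexicon word (which is why *Visits* in the example is scored as a verb, not
swallowed as a surname). Headlines are typically title-cased, so
capitalization alone is deliberately given no weight. The contract is the
same as for a statistical tagger — non-overlapping typed character spans, an
explicit error when no backend is available — and `backend =` accepts a
user-supplied tagger. Consequence for interpretation: entity recall on real
news text is lower than spaCy's, so absolute exclusion rates and scores on
real archives will differ from those of a statistical tagger; every
downstream stage is indifferent to which backend produced the spans.

## Validation statistics

`apply_rater_qc()` reproduces the panel quality-control rules: raters are
dropped when their calibration ratings correlate below 0.2 with the
leave-one-out mean of the other raters, when all their ratings are constant,
when they fail the attention check, or when they revoke consent. "Don't
understand" responses are removed before any statistic — they are not scale
values.

`compute_icc()` uses the **one-way random-effects** decomposition: each
headline is rated by a different random subset of raters, so rater identity
is not a crossed factor and two-way variants are not identifiable. For the
unbalanced design the variance decomposition uses the effective group size
$k_0 = (N - \sum n_i^2/N)/(n-1)$, and the averaged-rating reliability is the
Spearman--Brown step-up of the single-rating ICC at $k$ = the mean number of
ratings per headline. With all ratings identical the decomposition is
degenerate and the function errors rather than returning 0/0.

`stratified_sample()` draws equally from four score bins (0--2.5, 2.5--3,
3--3.5, 3.5--5 by default), restricted to headlines of 14--16 words, because
perceived concreteness correlates with expression length.

## Preparing archives for analysis

Within a test, only packages sharing an image are causally comparable:
`split_by_image()` partitions each test by image into derived tests, and
`filter_valid()` keeps partitions with at least two distinct headline
strings (after whitespace normalization; case differences count as
distinct) once scorer-excluded packages are dropped.

`standardize_concreteness()` builds the model predictors. Headline
concreteness is centered at its own test's mean and divided by **two**
standard deviations, where the SD is that of the group-mean-centered values
over the whole analysis sample. Two consequences drive the design:
group-mean centering makes the individual-level predictor uncorrelated with
the group-level moderator by construction, and the 2-SD scale makes
`hc = +0.5` exactly "one raw SD above the test mean", which is the unit in
which the headline results are quoted. The moderator (test concreteness
mean) stays on the raw 0--5 scale. Grand-mean centering is available as a
sensitivity option.

## The multilevel model

`fit_binomial_glmm()` fits

$$\mathrm{logit}(p_{ij}) = (\beta_0 + \upsilon_{0j}) + (\beta_1 +
\upsilon_{1j})\,hc_{ij} + \beta_2\, mtc_j + \beta_3\, hc_{ij}\,mtc_j,
\qquad y_{ij} \sim \mathrm{Bin}(n_{ij}, p_{ij})$$

with a full 2×2 covariance for $(\upsilon_{0j}, \upsilon_{1j})$, via
`lme4::glmer` with the bobyqa optimizer and the Laplace approximation. Each
headline enters as one binomial observation (clicks, impressions) — the
likelihood is identical to disaggregated Bernoulli rows and desk-scale
feasible. Wald covariance, 95% intervals and p-values are reported on the
log-odds scale. A binomial model has no additive residual; the variance of
the outcome is carried entirely by the binomial term and the random effects.

Numerical choices worth knowing:

* **Likelihood verification.** `marginal_loglik()` evaluates the marginal
  log-likelihood at *fixed* parameters two ways: a from-scratch Laplace
  approximation (damped Newton for each group's posterior mode) and adaptive
  Gauss--Hermite quadrature over the bivariate random effect (tensor grid,
  mode-centered, Golub--Welsch nodes). The two agree to $10^{-3}$ on small
  fixtures, and the Laplace route agrees with lme4's deviance at the fitted
  parameters. This is the package's defense against silently wrong
  integration.
* **nAGQ = 0 in the harnesses.** The simulation harnesses
  (`recovery_harness`, `estimate_power`, and the simulation-based acceptance
  criteria) use lme4's cheaper nAGQ = 0 approximation. At archive scales of
  interest (hundreds of binomial observations with thousands of trials
  each), estimates and Wald SEs agree with Laplace to about three decimals
  while running ~8× faster; single fits default to Laplace.
* **Convergence** is reported as a flag (optimizer status plus lme4's
  convergence messages); singular random-effect fits are reported, not
  fatal.

## Moderation analysis

The conditional effect of headline concreteness at moderator value $m$ is
$\omega(m) = \beta_1 + \beta_3 m$ with delta-method variance
$v_{11} + m^2 v_{33} + 2m\,v_{13}$. `johnson_neyman()` solves
$\omega(m)^2 = z_c^2\,\mathrm{var}(\omega(m))$ in closed form (a quadratic;
the tests verify the roots against a $10^{-4}$ grid search) and classifies
where the slope is significant; with a negative interaction the slope is
significantly positive below the lower bound and significantly negative
above the upper bound. The critical value defaults to the large-sample 1.96
and is configurable (the degrees-of-freedom convention of the original
online calculator is not stated, so we do not chase its exact bounds).
`holm_adjust()` applies the step-down correction over the three-hypothesis
family (interaction; slope at the observed minimum; slope at the observed
maximum) by default.

## The synthetic generator: what it emulates, what it does not

`generate_archive()` produces archives in the public dialect
(`clickability_test_id`, `headline`, `eyecatcher_id`, `impressions`,
`clicks`) with known ground truth. Stated-world defaults: tests of 2--5
packages with weights (0.10, 0.15, 0.40, 0.35) — "usually 4--5"; test-level
mean concreteness truncated-normal(3.08, 0.27) on [0, 5], matching the
observed moderator landmarks (2.81 / 3.08 / 3.35); Table-2-scale fixed
effects (−4.929, 0.168, 0.102, −0.058) and random-effect SDs (0.6534,
0.3651); one image per test. Where nothing is printed we chose once:
within-test headline SD of 0.35 raw units (headline variants of one article
differ moderately), impressions log-normal with median 4000 and sdlog 0.7
(typical mid-size A/B arms), random-effect correlation 0. Synthetic
headlines are strings of generated lexicon words that the real scorer maps
*exactly* back to the assigned concreteness (verified to $10^{-9}$ in the
tests), so the text path can be exercised end to end.

What the generator does **not** emulate: real entity mentions, slang and
coinages (so scorer exclusions are exercised by English fixtures, not by the
generator), position effects, temporal drift, and audience heterogeneity. A
green parameter-recovery run therefore establishes that the estimation
machinery is correct under the stated model — not that the model is true of
any particular archive.

`recovery_harness()` runs generate → prep → fit → probe per replicate and
reports bias, RMSE, and 95% CI coverage; by default it feeds the
ground-truth scores to the prep stage rather than re-tokenizing thousands of
synthetic headlines per replicate (the scorer's exactness on these strings
is established separately; `rescore = TRUE` forces the full text path).
`estimate_power()` estimates the probability that all three Holm-corrected
hypothesis tests reject jointly, over a grid of archive sizes, with an
isotonic smoothing of the raw power curve. The original pilot power
simulation is unpublished; this harness is a principled stand-in, not a
replication of its "3,500 experiments for 99% power" figure.

## Degenerate inputs and tie-breaks

* Lexicon rows outside [0, 5] or unparseable are rejected (warning with
  count); an all-rejected file is an error, and absent words are `NA`, never
  a default rating. Duplicate headwords: last occurrence wins.
* Bigram lexicon entries are stored but matched only if tokenization emits
  them as single units; there is no bigram re-assembly pass.
* "Three or more letters" counts alphabetic characters only.
* Zero-impression packages are excluded from CTR summaries and counted
  separately; `clicks > impressions` rows are invalid and dropped at read
  time.
* A rater with fewer than two usable calibration responses has an undefined
  calibration correlation and is excluded by default (`unevaluable = "keep"`
  retains them).
* `standardize_concreteness()` errors on zero SD (all headlines identical)
  instead of emitting infinities; re-standardizing standardized data is a
  no-op.

## Known limitations

* The gazetteer entity backend trades recall for determinism; real-archive
  exclusion rates and entity coverage will differ from a statistical tagger.
* The rule-based inflection fallback covers regular English morphology only;
  irregular plurals/verbs resolve only if the lexicon lists them.
* Wald intervals and the normal-theory Johnson--Neyman bounds are
  large-sample devices; at small numbers of tests their coverage dips
  slightly below nominal, which is visible in the recovery harness.
* Reported archive-dependent quantities (8977 tests, bounds 2.58/3.06, ICCs
  0.26/0.79, r = 0.61) require the request-only archive and raw ratings;
  this package reproduces the machinery and verifies it on synthetic truth,
  and computes those statistics only when the real data are supplied.
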