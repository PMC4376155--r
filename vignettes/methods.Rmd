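---
title: "Methods: lexicon sentiment, state geolocation, and the enrollment model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lexicon sentiment, state geolocation, and the enrollment model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`acasent` implements a complete, testable version of an infodemiology
analysis that links the sentiment of Affordable Care Act (ACA) tweets to
state-level health-insurance-marketplace enrollment. This vignette is the
package's own account of the statistical machinery, the design choices
made where the design was genuinely open, and what the synthetic-data
generator does and does not emulate.

## The sentiment model

Each tweet is scored against a word-weight lexicon in the dialect of the
NRC hashtag sentiment lexicon (tab-separated `word weight` pairs, positive
weights for positive sentiment). The score is a frequency-weighted sum:

$$\mathrm{score}(t) \;=\; \sum_{w \in t} \mathrm{weight}(w)\,
\frac{n_w(t)}{N(t)},$$

where $n_w(t)$ is the number of occurrences of word $w$ in tweet $t$ and
$N(t)$ is the total (non-unique) token count. Two consequences matter:

* **Out-of-vocabulary words score zero but count in $N(t)$.** The
  denominator is the number of words in the tweet, not the number of
  lexicon words, so a long tweet with one positive word scores lower than
  a short one.
* **The score depends only on relative frequencies.** It is invariant to
  token order and to duplicating every token; tests assert both, and an
  independent brute-force token loop reproduces the vectorized
  implementation to 1e-12.

Tokenization lowercases, splits on whitespace, strips leading/trailing
punctuation (keeping a leading `#` or `@`), leaves URLs intact, and
expands every `#tag` to the bare `tag` as well — the lexicon is matched
with and without the `#`, and both forms count in $N(t)$. Negation,
emoji and any model beyond this bag-of-words formula are deliberately out
of scope.

Raw scores are Z-standardized across all scored tweets in a run — keyword,
handle-mention and random-sample sub-corpora pooled — using the
*population* SD for determinism (at corpus scale the sample/population
distinction is far below any reported precision). Pooling means every
group contrast is expressed in the same SD units. A state's sentiment is
the mean Z score of the keyword tweets geolocated to it.

Group contrasts use Welch's unpaired two-sample t test. The compared
corpora (about a million keyword tweets versus an equally sized random
sample; handle corpora of different sizes) have no pairing structure, so
a paired test is not definable here; the unpaired unequal-variance test is
the defensible choice and is what `compare_groups()` implements.

## Geolocation

Coordinates take precedence over profile text. Points are tested against
packaged simplified state polygons (a handful of vertices per state,
mostly conservatively shrunk bounding boxes with hand-drawn outlines for
irregular states). This resolution is adequate because the analysis needs
state *membership* for points well inside a state — synthetic corpora use
interior representative points — not exact borders. Where simplified
borders overlap, the lexicographically first state code wins; the rule is
arbitrary but deterministic, and tests pin it.

Free-text profile locations are matched with the precedence **full state
name > two-letter abbreviation > top-60 city name** over case-folded,
punctuation-split text:

* State names are matched as whole phrases; the earliest match in the
  string wins (so "West Virginia" is WV, not VA), with ties broken by
  state code. "Washington DC" and "Washington, D.C." are special-cased to
  DC ahead of the Washington-state name.
* Abbreviations only count when uppercase and standalone (`"PA"`) or
  following a comma (`"Philadelphia, pa"`). This trades recall for
  precision — lowercase "in", "me", "hi", "ok" never fire as states —
  mirroring the high audited accuracy such pipelines report.
* City names come from a packaged list of the 60 most-populated US cities
  (2013-era census ranking; the list is a plain CSV and swappable). An
  ambiguous city name maps to its highest-population bearer.

One documented quirk of the precedence: a city whose name *contains* a
state name resolves to that state ("Kansas City" alone resolves to KS).
The synthetic generator therefore plants only unambiguous city strings.
A 400-string audit of unambiguous names, abbreviations and cities — the
same design as a manual audit of an automated geocoder — must resolve at
100% accuracy in the test suite.

## The enrollment model

Percent eligible enrolled is `100 * plan_selections / eligible`. Before
fitting, states more than 2.5 SD *above* the mean enrollment rate are
excluded (upper tail only; mean and SD computed over all states). Two
properties of this rule are worth knowing:

* It is the rule under which a single extreme state (the Vermont case in
  the motivating study) is dropped.
* **Masking bounds it at small n**: the largest possible standardized
  deviation in a sample of n is $(n-1)/\sqrt{n}$, so with $n \le 8$ a
  2.5-SD rule can never fire, and a planted 3-SD outlier needs roughly
  $n \ge 50$ to clear the threshold its own presence inflates. Unit tests
  use larger planted offsets at small n for exactly this reason.

The model is OLS of percent enrolled on state mean sentiment (optionally
plus Medicaid-expansion and marketplace-type dummies, fitted one at a time
as adjusted runs, plus a both-covariates run), with heteroskedasticity-
robust **HC1** sandwich standard errors — the convention of the "robust"
default in the major commercial statistics packages. The headline effect
is reported per 0.10 sentiment units (`slope / 10`) with a 95% CI using
the t distribution on $n - p$ degrees of freedom; at ~50 states the normal
quantile would be noticeably anticonservative. The outcome is percentage
points by default; a log-outcome variant is available
(`outcome = "log"`), since the phrase "an X% increase in enrollment" is
ambiguous between the two scales and the percentage-point reading is the
one consistent with a CI reported on the same scale.

HC1 + t CIs at $n = 50$ still undercover slightly: measured coverage of
the package's 95% CI under Gaussian noise is about 94.3% over 5000
replicates. That is a property of the estimator, not a defect of the
implementation — the HC1 matrix itself matches a from-the-definition
sandwich oracle to 1e-10.

## Rater validation

Interrater reliability uses the intraclass correlation computed from
two-way ANOVA mean squares. The default form is **ICC(2,1)** (two-way
random effects, absolute agreement, single rater): raters are treated as
a random sample and systematic rater mean differences count against
agreement. ICC(3,1) (consistency) is available behind a flag; tests
assert the characteristic difference — consistency is invariant to a
rater mean shift, agreement is not. When the between-subject variance is
zero the coefficient is undefined and reported as 0 with a warning. The
human consensus is the arithmetic mean of the two raters, and its
correlation with the lexicon scores is ordinary Pearson.

## The synthetic-data generator

The generator exists so that every stage has a ground truth. Tweets are
*not* natural language: each is a fixed number (default 20) of i.i.d.
category draws — weights {+2, +1, −1, −3} plus neutral out-of-vocabulary
fillers — followed by one tag token (a collection term, an `@handle`, or
a neutral filler for the random sample). A group's word distribution is a
convex combination of a "negative" and a "positive" anchor mixture, so
the mean lexicon weight is linear in the mixing parameter and any target
mean score maps to exactly one mixture. Expected scores, their variances,
and therefore every planted contrast are analytic.

What the defaults emulate (the conditions of the motivating study):
50 states + DC; a keyword corpus 0.44 SD below an equally sized random
sample; ACA-tagged tweets 0.46 SD above Obamacare-tagged ones; the
federal-handle corpus 0.20 SD below the state-handle corpora, with the
handle corpora about 3.5% of the keyword corpus; 46% of keyword tweets
carrying resolvable geography (planted deterministically, so the fraction
is exact); enrollment averaging 23.5% with a planted slope of 87
percentage points per sentiment SD (8.7 per 0.10 units) and 8 points of
state-level noise; one state (Vermont) planted 3 SD above the mean; and a
300-tweet two-rater study with a score-human correlation of 0.26 and
rater noise calibrated by simulation so the discretized population
ICC(2,1) is about 0.72. Not all published quantities can hold
simultaneously under a single Gaussian model — with this sentiment spread
and noise the regression is better powered than the original (smaller p,
narrower CI); the defaults prioritize the enrollment mean/SD, the planted
slope, and the group contrasts.

Choices a user should know:

* **One RNG stream per stage**, derived from the master seed and the
  stage name, so changing the rater design never reshuffles the corpus.
  Identical seed and configuration reproduce every output file byte for
  byte.
* **State effects are evenly spaced** over a configurable range. The
  study preset uses a narrow, realistic range (0.35 within-group SD end
  to end); the `scenario_recovery()` preset uses 3.8 SD — the widest the
  word model admits — so adjacent states differ by ~4 standard errors at
  5000 tweets/state and the full ranking is recovered with
  near-certainty.
* **Enrollment is generated from the realized state sentiment** (the
  package's own scoring of the generated corpus), centered so the
  intercept is the mean rate; the planted slope is therefore exact with
  respect to the sentiment a subsequent pipeline run recomputes.
  Rates are floored at 0.05% (enrollment rates are positive); noiseless
  configurations stay clear of the floor and recover the slope to 1e-8.
* **Integer conversion**: the written CSV stores integer plan selections
  and eligible counts; recomputed percentages differ from the exact
  generated ones by under 1e-3 points at the default eligible-population
  scale.

What the generator does **not** emulate: natural-language variation
(negation, sarcasm, emoji), tweet-length variation, spatial correlation
between neighboring states, confounding between sentiment and the policy
covariates (flags are assigned independently), and measurement error in
eligible-population estimates. Passing tests demonstrate that the
pipeline's machinery is correct and calibrated under known conditions;
they say nothing about lexicon validity on real tweets, which is exactly
why the rater-validation stage exists.

## Problem sizes and numerical conventions

The default test suite analyzes corpora of 10^4–10^5 synthetic tweets and
runs 5000-replicate calibration studies for the regression (null
rejection rate and CI coverage) and a single full-scale recovery scenario
(50 states x 5000 tweets/state, about half a million generated tweets
including the comparator sample); these sizes keep the whole suite within
a coffee break on one core while leaving Monte-Carlo noise well below
every asserted margin. Ties in quartile binning go to the lower bin; bins
differ in size by at most one. Degenerate inputs error early and
specifically: zero-variance corpora cannot be Z-standardized, constant
vectors have no Pearson correlation, rank-deficient designs are refused,
and an eligible population of zero is an input error, not an Inf.
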