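---
title: "Estimating brain age from smartphone keystroke dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating brain age from smartphone keystroke dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Typing on a phone is a small, continuously repeated motor and cognitive
task. Its kinematics — how fast consecutive keys follow each other, how
long a burst of typing lasts, how often the user corrects themselves —
change with age. `typeage` builds a behavioral *brain age* from these
signals: a random-forest regression maps per-subject typing summaries to
chronological age, and the per-subject *raw prediction error*
(predicted minus actual age, the brain-age gap) becomes a candidate
marker of pathology. The package contrasts that gap between subjects
screening positive and negative for bipolar disorder on the Mood
Disorders Questionnaire (MDQ, positive at a symptom score of 7 or more),
motivated by the neuroprogression hypothesis that bipolar disorder
accelerates age-associated neuropathology.

Only keypress *metadata* enter the analysis: a subject id, a timestamp,
and the keypress category (alphanumeric, backspace, autocorrect, other).
No typed content is ever represented.

## From raw events to features

**Sessions.** Each subject's event stream is tokenized into typing
sessions by a gap rule: consecutive events less than 5 seconds apart
belong to the same session. The rule for joining is strict (`< 5 s`), so
a gap of exactly 5 seconds starts a new session; events with identical
timestamps always join. The resulting partition is the unique
maximal-run partition, which the test suite verifies against a
brute-force oracle.

**Session metrics.** Six quantities summarize each session: keypress
count, mean and median interkey time (undefined for single-keypress
sessions, which the tokenizer deliberately keeps), autocorrect rate,
backspace rate (both computed over all keypress types), and session
duration. Interkey times include transitions into and out of backspace
and autocorrect events; distinguishing transition types is out of scope
here.

**Subject features.** For each of the six session-level series the
package computes the across-session mean, median, sample (n−1) standard
deviation and *unscaled* median absolute deviation — deliberately
without the 1.4826 normal-consistency factor that many MAD
implementations apply by default — plus the sample entropy of the
chronologically ordered series: 30 features per subject
(`typing_feature_names()`). Summaries drop missing elements; the sd of
a length-1 series is missing.

**Sample entropy.** SampEn(m, r, tau) = −ln(A/B), where B counts pairs
of length-m templates within Chebyshev distance r and A counts the same
for length-(m+1) templates, self-matches excluded, both counts over
start points 1..n−m. Defaults follow the standard choice m = 2,
r = 0.2 · sd(series), tau = 1. Tying r to the series sd makes the
estimate invariant under positive affine transforms, which the tests
assert exactly. Two numerical choices matter: series shorter than
`min_len = 10` (configurable) return a missing value, because m = 2
needs at least 4 points to be defined at all and very short series give
wild estimates; and A = 0 or B = 0 also returns missing rather than
±Inf, keeping the estimator finite. Missing features are later imputed
from training-set medians only, so no information leaks across the
split.

**Inclusion filter.** Subjects must contribute "12 weeks worth" of
typing. The rule is implemented as: compute each subject's daily
keystroke rate (total keypresses / days with any activity), take the
cohort median of those rates, and include a subject iff their total
keypress count is at least `12 × 7 ×` that median, with boundary
equality including. This is one defensible reading of a rule whose
exact formula admits alternatives; it is isolated in
`filter_participants()` so another convention can be swapped in. Note a
consequence probed by the tests: when every subject is observed for
exactly 12 weeks, inclusion reduces to having an above-median daily
rate, so roughly half of such a cohort is excluded.

## The age models

Two stepwise random-forest regressions (via the `randomForest` package)
predict chronological age: Model 1 from the 30 typing features, Model 2
from those plus the `not_male` gender indicator and MDQ screen status
(32 predictors). Subjects are split 75:25 into training and validation
by simple random, unstratified sampling (`ceiling(0.75 n)` train). The
`mtry` parameter is tuned by grid search over 1–30 with repeated k-fold
cross-validation (default 10-fold × 3 repeats); fold RMSEs are averaged
— not pooled — and the smallest `mtry` wins ties, preferring the
simpler model. Forests use 500 trees by default and keep their in-bag
records so out-of-bag quantities remain computable. Age is derived as
`reference_year − birth_year`, with the reference year defaulting to
the calendar year of the latest observed event.

Performance is reported as validation RMSE, Breiman's pseudo R² —
`1 − MSE/Var(age)` with the population-variance denominator, so the
identity `pseudoR² = 1 − RMSE²/Var` holds exactly — and median absolute
error. The two models are compared by a paired two-sided Wilcoxon
signed-rank test on absolute errors. Group contrasts by screen status
use two-sided Wilcoxon rank-sum tests on raw and absolute errors; these
two p-values form one Holm–Bonferroni family, while the model
comparison is reported unadjusted (configurable). Rank tests use the
conventional exact null for small samples without ties and the normal
approximation with continuity correction otherwise.

## Interpretation

**Permutation importance.** For each feature, the increase in
out-of-bag MSE after permuting that feature's column, averaged over 5
seeded permutations; every training observation is evaluated only on
trees where it was out of bag. Importance is a credit measure, not a
direction: duplicated features share credit, which the tests
demonstrate.

**Accumulated Local Effects.** First-order ALE curves average *local*
finite differences of the prediction within equal-count quantile bins,
accumulate them, and center so the count-weighted mean effect
(interpolated at bin midpoints) is zero. Because differences are taken
within bins, the curve of a linear predictor recovers its slope exactly
even when features are strongly correlated — the property that makes
ALE preferable to partial dependence for the highly collinear typing
features. Second-order surfaces accumulate mean second differences on a
2D quantile grid, subtract the implied first-order components, and are
doubly centered; an additive model yields an identically zero surface.
Duplicate quantile edges are collapsed (reducing the bin count), empty
2D cells borrow the nearest non-empty cell's value, and a constant
feature is an error rather than a silent zero curve.

## The synthetic cohort

The study's raw keystroke streams are not deposited, so the package
ships a generator (`generate_cohort()`) producing event streams with the
statistical structure the analysis assumes. Its defaults are the study
conditions: 344 subjects, 227/344 screen-positive, ages uniform on
18–88, 84 days (~12 weeks) of observation, and MDQ scores drawn 7–13
for positives and 0–6 for negatives. Mechanisms, chosen as the simplest
that reproduce the qualitative age effects the analysis detects:

* **Sessions** arrive by a per-day Poisson process (default mean 6/day)
  scaled by a per-subject lognormal activity multiplier (sdlog 0.6),
  giving the heavy-tailed total-keypress distributions typical of
  passive phone data. Consecutive sessions are separated by at least
  5 s by construction, so tokenization recovers the generator's session
  boundaries exactly (tested).
* **Interkey times** are lognormal — positive and right-skewed, as
  typing latencies are — with mean rising linearly from 0.22 s at age
  18 by 0.004 s per year of *effective typing age*, plus subject- and
  session-level noise. Within-session gaps are truncated below 5 s so
  sessions never split.
* **Session length** emerges from a geometric keypress count whose mean
  tracks a target duration rising 0.45 s per year from 20 s at age 18.
* **Backspace regularity**: the session-to-session backspace
  probability follows a logit-scale AR(1) signal whose persistence
  increases with effective typing age. Older subjects' backspace-rate
  series are therefore smoother and more predictable — lower sample
  entropy — while younger subjects' series are dominated by
  session-level noise and binomial keypress noise, hence higher
  entropy. (Merely shrinking the series' variance would not move sample
  entropy, which is scale-invariant by construction; regularity must
  change through autocorrelation.)
* **Neuroprogression** is a single scalar: screen positives type like
  someone `brainage_offset_years` older (their *effective typing age*),
  the minimal mechanism that yields the raw-error asymmetry between
  groups. Chronological age and metadata are untouched.
* **Gender** has no effect on typing in the default generator; no
  gender effect on kinematics is quantified in the source analysis. The
  per-group `not_male` proportions (60% / 75%) only shape the metadata.

What the generator does *not* emulate: language structure, diurnal
typing-speed cycles, mood dynamics across days, or any fitted moments
of a real cohort. Passing tests therefore show that the pipeline
recovers the structure it assumes, not that real typing data carry this
much signal.

## Study-condition checks and problem sizes

The acceptance-style tests in `tests/testthat/test-acceptance.R`
exercise the whole chain at sizes chosen to keep a full run on one CPU
within minutes while leaving the checks well-powered:

* oracle equivalence for the tokenizer (1,000 random streams up to 500
  events), sample entropy (200 series of length 10–200 against an
  O(n²) template-counting oracle, 1e-10), the 30-feature engine (50
  simulated subjects, 1e-10) and both ALE orders (closed forms and a
  brute-force oracle);
* age-signal recovery: 400 subjects, ages 18–80, strong slopes
  (0.008 s/yr interkey, 0.8 s/yr session length), 14 observation days,
  full mtry grid 1–30 with 5-fold single-repeat CV and 250-tree
  forests; validation pseudo-R² must reach at least 0.3;
* offset recovery: a 6-year offset at 66% prevalence over 20 replicates
  (300 subjects, 200-tree forests, fixed mtry 10, typing-only model —
  including MDQ status as a predictor would let the forest absorb part
  of the planted offset), requiring the negative group's median raw
  error below the positive group's in at least 16/20 and rank-sum
  rejection in at least half; and a null calibration with no offset
  over 200 faster replicates (100 subjects, 7 days, 60-tree forests)
  whose rejection rate must sit inside the 95% binomial envelope of
  the nominal 5% level;
* bit-reproducibility of two pipeline runs under one master seed.

`scripts/acceptance.R` runs the pipeline once at study shape: 688
simulated subjects with 84-day windows feed the 12-week filter, leaving
roughly 344 analyzable subjects (the equal-window consequence noted
above), with the 66% prevalence, a planted 6-year offset, a mean of 3
typing sessions per day (a light-typist cohort keeping the simulated
stream around 10 million events), generator defaults otherwise, and
5-fold single-repeat tuning over the full 1–30 grid. It writes the validation metrics of both models, the group
medians and rank statistics, and the paired model comparison.

## Reproducibility and design choices

One `master_seed` derives per-stage seeds as
`(master_seed + 1000003 · stage) mod (2³¹ − 1)`, so stages are
independently re-runnable and two runs with the same seed are
byte-identical (tested). Other choices made where the design was open:

* millisecond timestamps are detected by magnitude (> 10¹¹) and
  converted to seconds, since the 5-second rule is stated in seconds;
* unknown keypress labels map to `other` with a warning count; rows
  with unparseable timestamps are rejected with full accounting, never
  silently dropped;
* the split requires at least 8 subjects so both partitions are
  non-empty and the validation set can host a rank test;
* prediction tolerates subjects with all features missing (they get the
  training-median vector) but refuses tables missing a predictor
  column;
* `tune_mtry` averages fold RMSEs over folds and repeats; pooling
  residuals instead is a one-line change localized in that function.

## Limitations

The brain-age gap here inherits every caveat of regression-to-the-mean:
a model trained on a mixed cohort underpredicts old ages and
overpredicts young ones, so group differences in *raw* error must be
read against group age distributions. The synthetic cohort plants a
uniform offset, which no real disorder produces. Sample entropy on
short session series (tens of sessions) is noisy, and its missing-value
rule censors exactly the least-active subjects. None of the numbers
produced on simulated cohorts estimate the performance attainable on
real keystroke data.
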