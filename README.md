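# typeage

Brain-age estimation from smartphone keystroke dynamics.

Typing on a phone leaves a continuous behavioral trace — when each key
was pressed and whether it was an alphanumeric key, a backspace or an
autocorrection, with no content ever recorded. `typeage` turns such
keypress metadata into a behavioral *brain age*: event streams are
tokenized into typing sessions (consecutive keypresses < 5 s apart),
each subject is summarized by 30 kinematic and regularity features
(means, medians, standard deviations, unscaled MADs and sample
entropies of six session-level series), and tuned random-forest
regressions predict chronological age from them. The per-subject **raw
prediction error** — predicted minus actual age, the *brain-age gap* —
is then contrasted between subjects screening positive and negative for
bipolar disorder on the Mood Disorders Questionnaire (MDQ, positive at
a symptom score ≥ 7), the neuroprogression hypothesis being that the
disorder accelerates age-related change, so affected subjects should
"type older" than they are.

The core quantities, for predictions ŷ of ages y:

* RMSE = √(mean((ŷ − y)²)); Breiman's pseudo R² = 1 − MSE/Var(y);
  median absolute error = median(|ŷ − y|).
* SampEn(m, r, τ) = −ln(A/B), with B the number of length-m template
  pairs within Chebyshev distance r = 0.2·sd(series), A the same for
  length-(m+1); defaults m = 2, τ = 1.
* Group contrasts: two-sided Wilcoxon rank-sum tests on raw and
  absolute errors, Holm–Bonferroni adjusted as one family; model
  comparison by paired Wilcoxon signed-rank on absolute errors.
* Interpretation: out-of-bag permutation importance (ΔMSE) and first-
  and second-order Accumulated Local Effects, implemented natively.

Because the study's raw keystroke data are not deposited, the package
includes a synthetic-cohort generator (`generate_cohort()`) that
emulates the assumed structure — interkey times and session lengths
rising with age, backspace-rate regularity rising with age, a
controllable brain-age offset δ for screen positives — so the whole
pipeline is testable end to end.

## Worked example

Simulate a cohort with a planted 6-year brain-age offset in screen
positives and run the full analysis:

```r
library(typeage)

cfg <- run_config(
  cohort = cohort_params(n_subjects = 120, n_days = 14,
                         sessions_per_day_rate = 4,
                         brainage_offset_years = 6),
  tune = tune_config(mtry_grid = c(5, 10, 15), cv_folds = 5,
                     cv_repeats = 1, n_trees = 200),
  min_weeks = NULL, master_seed = 7L)
res <- run_pipeline(cfg, "runs/demo")

res$evaluation[res$evaluation$partition == "validation", ]
#>                model_id  partition  n     rmse pseudo_r2 median_abs_error chosen_mtry
#>      model1_typing_only validation 30 8.942386 0.8421455         6.235125          10
#>  model2_plus_gender_mdq validation 30 8.848347 0.8454481         6.201917          10

res$group_comparison
#>  comparison_id statistic_name statistic      p_raw median_positive median_negative p_adjusted
#>      raw_error     rank_sum_W       164 0.01706409        8.582792        1.803708 0.01706409
#>      abs_error     rank_sum_W       174 0.00429118        8.582792        3.381917 0.00858236

head(as.data.frame(res$importance), 3)
#>              feature delta_mse rank
#>  mean_session_length  74.86694    1
#>   mad_session_length  19.01875    2
#>    sd_session_length  17.88163    3
```

Reading the output: both models explain most of the simulated age
signal (validation pseudo-R² ≈ 0.84, RMSE ≈ 8.9 years). The planted
offset surfaces exactly where the gap analysis looks for it — the
median raw error of screen positives (+8.6 years, "typing older") sits
above that of screen negatives (+1.8 years), and the rank-sum test
rejects at the 5% level after Holm adjustment. Session length and
interkey-time summaries dominate the importance ranking, as expected
from the generator's age mechanisms. The run directory also receives
`features.csv`, per-model tuning traces and predictions,
`evaluation.json`, `group_comparison.json`, ALE/importance/boxplot
figures under `figures/`, and a `manifest.json` with all derived seeds;
rerunning with the same `master_seed` reproduces every file
byte-for-byte.

A thin command-line wrapper is installed with the package
(`system.file("cli", "typeage", package = "typeage")`) with
`simulate`, `featurize` and `run` subcommands driven by a YAML config
(see `read_run_config()`).

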