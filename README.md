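# bloodclock

Hematological aging clocks from routine blood tests, and what they say
about smoking.

`bloodclock` is an R package plus a numbered analysis workflow for the
question: *does a smoker's blood chemistry read older than their years, and
by how much?* It implements the full pipeline — synthetic cohort
generation, tree-ensemble feature selection, missing-marker reconstruction,
age and smoking-status prediction, and age-acceleration statistics — for
biostatisticians and epidemiologists who want an end-to-end, testable
version of the blood-biochemistry aging-clock design. The study population
it emulates (149k adults, up to 66 biochemistry and cell-count markers,
33% smokers, median age 55) is private health data, so every stage runs
against a synthetic cohort with a *planted, known* smoking effect and is
validated by parameter recovery.

## The statistics at the core

**Arbitrage feature importance.** Many bagged-tree models (default 320,
80 trees each) are trained on distinct marker subsets; a marker's score is

    FI_j = sum over models i containing j of  q_ij / MAE_i

where `q_ij` is the marker's mean-decrease-accuracy (permutation
importance) in model *i* and `MAE_i` that model's held-out error — markers
that matter *in accurate models* rise to the top. Nested feature sets are
cut where adding the next marker would cost more than 10% of the eligible
subjects.

**The log2 aging ratio.** With chronological age `y` and clock prediction
`y_hat`, the per-sample statistic is `log2(y_hat / y)`: 0 is on-clock, +1
reads twice its age, −1 half. Cells (age group × sex × smoking) are
compared by two-tailed Mann–Whitney tests; a cholesterol-ratio (>4) ×
fasting-glucose (>5 mmol/L) quadrant view covers cardiovascular risk
strata. Supporting metrics: Pearson r, R², MAE, boundary-inclusive
ε-accuracy, precision/recall/F1, and the biweight midcorrelation for
robust marker–age association.

## Worked example

Train a clock on nonsmokers, predict everyone held out, and read off the
planted acceleration (female smokers age ×2, male ×1.5 below 55):

```r
library(bloodclock)
cohort <- generate_cohort(generator_config(n_subjects = 2000, seed = 1))
core <- marker_names(cohort)[colSums(is.na(cohort[marker_names(cohort)])) == 0]
spec <- split_spec(seed = 2)                 # 80/20, stratified by decade
parts <- split_train_test(cohort[cohort$smoking == 0, ], spec)
clock <- train_age_model(parts$train, c(core, "sex"), spec)
pred <- predict_age(clock, rbind(parts$test, cohort[cohort$smoking == 1, ]))
regression_metrics(pred[pred$smoking == 0, ])
#> Age-prediction report (n = 268)
#>   MAE       : 2.641 years
#>   r         : 0.988
#>   R^2       : 0.9749
#>   eps-acc   : 1.000 (eps = 10 years)
ratio <- log2_aging_ratio(pred)
below <- pred$age < 55
mean(ratio[below & pred$smoking == 1 & pred$sex == 0])  # 0.987  (planted 1.000)
mean(ratio[below & pred$smoking == 1 & pred$sex == 1])  # 0.592  (planted 0.585)
mean(ratio[!below & pred$smoking == 1])                 # -0.011 (planted 0)
```

The clock never saw a smoker, yet female smokers under 55 read almost
exactly twice their age (log2 ratio ≈ 1) and male smokers about one and a
half times (≈ 0.585); at and above the plateau age of 55 the effect is
gone — exactly the structure the generator plants. On held-out nonsmokers
the clock is nearly unbiased, which is what makes the ratio interpretable.
`group_aging_summary(pred)` gives the per-cell table with Mann–Whitney
p-values, and `assign_risk_groups()` / `risk_group_aging_summary()` the
risk-quadrant breakdown.

Note the synthetic panel is deliberately low-noise so recovery tests have
teeth (see the methods vignette in `vignettes/`); real blood panels yield
markedly noisier clocks.

## Acceptance script

`scripts/acceptance.R` recomputes the pipeline's checkable quantities from
scratch by running the installed package: the log2 aging ratio at the two
worked points (a twofold and a half prediction), the number of arbitrage
models fitted at default settings on a fresh 500-subject cohort, the
complete-marker count after reconstructing the packaged nested-space
fixture, and the default cohort's median age, smoker percentage and marker
count. Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
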