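---
title: "Blood-biochemistry aging clocks and smoking-associated acceleration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood-biochemistry aging clocks and smoking-associated acceleration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Routine blood biochemistry and cell-count panels carry an aging signal: many
markers drift with age in a roughly monotone way (glycated hemoglobin, urea,
fasting glucose and ferritin among the strongest). A model that maps a blood
panel to a predicted ("biological") age — an *aging clock* — turns that drift
into a per-person statistic. Applied to smokers and nonsmokers, the clock
asks a concrete question: does a smoker's blood read older than their years?

The administrative dataset this analysis was designed around (149k adults,
up to 66 markers, 33% smokers, median age 55) is private health information
and cannot ship with the package. `bloodclock` therefore pairs every stage
of the analysis with a synthetic-cohort generator whose planted structure is
known exactly, so each stage can be tested as a *parameter-recovery*
problem rather than against unreachable reference values.

## Pipeline overview

1. **simulate** — generate a cohort with a planted smoking effect;
2. **select features** — rank markers by arbitrage importance over many
   tree-ensemble models and pick nested marker sets that keep many subjects;
3. **reconstruct** — fill missing marker values by per-marker regression;
4. **age clock** — train an MAE-minimizing regressor on nonsmokers, predict
   everyone held out;
5. **aging ratio** — per-sample log2(predicted/chronological age), summarized
   by age group, sex, smoking, and cardiovascular-risk quadrant, with
   Mann–Whitney tests;
6. **smoking classifier** — predict smoking status from markers and sex;
7. **importance** — permutation feature importance and partial dependence.

The `analysis/` directory holds one numbered driver per stage; all
computation lives in the package.

## The synthetic cohort: a stated world

`generator_config()` fixes the cohort design; `default_marker_panel()` fixes
the marker model. Choices, with rationale:

* **Ages** are placed on a deterministic symmetric grid over [18, 92] and
  shuffled, so the median is exactly 55 for any n. This makes cohort-level
  checks deterministic rather than approximate.
* **Sex and smoking** are assigned by largest-remainder quotas inside
  10-year age groups: the smoker count is exactly `round(0.33 n)` and groups
  are balanced by construction, matching the matched design of the study
  population.
* **Biological age** B equals chronological age, except for smokers below
  the plateau age (55), where B = age × factor with factors 2.0 (female) and
  1.5 (male) by default — the planted analogue of the headline finding the
  package must be able to recover. The plateau is a hard cutoff by default
  (a linear taper is available) because the empirical effect disappears
  after 55.
* **Markers** are linear (optionally saturating) responses to B with
  additive Gaussian noise, plus a direct smoking offset on four markers
  (HDL −0.5 SD; hemoglobin, RDW, MCV +0.5 SD) so the smoking classifier has
  signal that does not pass through age acceleration. Offsets sit on
  markers with (near-)zero age slope so they do not bias the clock.
* **Signal-to-noise** is a deliberate calibration: the 22 fully observed
  "core" markers jointly determine B to about ±3 years (a linear fit
  reaches R² ≈ 0.98). Real clinical panels are far noisier (the study's
  clocks reach MAE ≈ 5.7 y, R² ≈ 0.56). The strong setting is needed
  because the recovery tests demand per-cell log2-ratio accuracy of ±0.1:
  with realistic noise, regression-to-the-mean near the age boundaries
  alone exceeds that band. A green recovery test therefore establishes
  that the *machinery* recovers planted effects without bias — not that
  the method would achieve this precision on real data.
* **Missingness** is MCAR and quota-exact per marker (0% on the 22 core
  markers, 5–25% on 24 markers, 30–60% on the 20 "reconstructable" ones).
  Real missingness is structured by test panels and clinics; co-missingness
  blocks are emulated only in the reconstruction fixture.

Not emulated, by design: inter-marker correlation beyond the shared
age/sex/smoking structure, longitudinal records, and survivorship
(differential mortality of elderly smokers). The last omission matters for
one result; see *Partial dependence* below.

## Arbitrage feature importance

Each candidate marker subset ("feature space") gets one bagged
regression-tree model (80 trees) predicting age from the subset's complete
cases, with a held-out 20% giving the model's MAE. The arbitrage score of a
marker is

$$FI_j = \sum_{i : j \in S_i} \frac{q_{ij}}{MAE_i},$$

where \(q_{ij}\) is the mean-decrease-accuracy of marker j in model i
(operationalized as permutation importance on the held-out split — the
estimator-agnostic reading of "mean decrease accuracy") and the division by
\(MAE_i\) up-weights importance earned inside accurate models. 320 spaces
are used by default. Because no description of the original space
construction survives, spaces are built as nested prefixes of the
candidates ordered by ascending missingness (maximizing eligible subjects
at each size) plus seeded random subsets of sizes 5 and up; only spaces
with ≥ 50 complete cases are emitted, so every space is trainable.

Feature sets are selected by a knee rule on the greedy FI ordering: a set
boundary is placed wherever adding the next-ranked marker would cost more
than 10% of the currently eligible subjects. Ties anywhere in the ranking
break by ascending marker name, making the selection order-independent.

The tree ensemble itself is a compact CART forest written for this package
(bootstrap resampling, per-node feature subsampling, variance-reduction
splits, depth-limited), compiled via Rcpp: no tree-ensemble package is
available in the target environment, so this standard component is built,
not bought.

## Reconstruction

Each partially missing marker is regressed by OLS on the fully observed
markers of its feature set plus age and sex, over the subjects where it is
observed (30–60% of the cohort for the markers worth reconstructing), and
predicted deterministically where missing. Targets are processed in
ascending-missingness order so earlier reconstructions can serve later
ones. Observed values are never overwritten, a provenance flag marks every
filled cell, and rows lacking a predictor stay missing and are counted. No
residual noise is added: the reconstruction is a conditional-mean fill,
which is what the downstream regressions want (multiple imputation and
uncertainty propagation are out of scope).

## The age clock and the smoking classifier

Both models share one estimator contract: z-score the marker features with
training-set statistics (never the held-out data), fit an estimator that is
deterministic given its seed, and predict on complete rows only. The
default estimator is a small fully connected network — two hidden ReLU
layers of equal width, width chosen from {16, 32, 64} by five-fold
cross-validation, minibatch Adam (batch 256), MAE loss for the clock and
binary cross-entropy for the classifier, early stopping on a held-back 15%
validation slice, and an average over three seed-varied networks for the
final fit (cheap variance reduction that visibly stabilizes the age
tails). A bagged-tree forest and a linear model satisfy the same contract
for cross-checks and fast tests.

Two deliberate deviations from the study-scale recipe:

* **Dropout defaults to 5%, not 35%.** At the study's scale (119k training
  samples, wide layers) 35% dropout is ordinary regularization. At desk
  scale it measurably biases the clock: trained with 35% dropout, the
  network compresses predictions toward the cohort mean (18-year-olds
  predicted ≈ 24, log2 ratio bias ≈ +0.3), an instance of the known
  train/inference mismatch of heavy dropout stacked through nonlinear
  layers. Early stopping supplies the regularization instead; the
  parameter remains exposed for anyone reproducing the heavy-dropout
  regime.
* **No gradient-boosted fallback.** No boosting package exists in the
  target environment; the bagged CART forest fills the tree-ensemble role.

The clock's two training designs are guarded: under the default
nonsmokers-only design, smokers in the training set or a smoking column
among the features is an error; the extended design (smokers included,
smoking status as a feature) lifts both restrictions explicitly. The
classifier always refuses the smoking column among its inputs.

## Evaluation metrics

For age prediction: Pearson r between true and predicted age; coefficient
of determination \(R^2 = 1 - SS_{res}/SS_{tot}\) (computed on held-out
data, so it can be negative); MAE in years; and ε-accuracy, the fraction of
predictions inside the **closed** interval \([y-\varepsilon,
y+\varepsilon]\) with ε = 10 years by default — a prediction exactly ε off
counts as correct, following the worked example that defines the metric.
For smoking: confusion counts with smoker as the positive class, accuracy,
precision, recall, and F1; metrics with zero denominators are reported as
`NA`, never as zero. All formulas are checked against independently coded
loop-based oracles to 1e-10 in the test suite.

## The aging-ratio analysis

The per-sample statistic is \(\log_2(\hat{y}_i / y_i)\): 0 is on-clock, +1
is "reads twice its age", −1 is "reads half its age". Summaries are means
(not medians) with SDs per (age group × sex × smoking) cell, matching the
mean-±-SD presentation the statistic is usually given. Numerical choices:

* Nonpositive predicted ages (possible for an unconstrained regressor) are
  excluded from ratio analyses and counted, never silently dropped.
* The smoker-vs-nonsmoker comparison within each (age group × sex) stratum
  uses a two-tailed Mann–Whitney test via `stats::wilcox.test`: exact when
  both groups have ≤ 50 tie-free observations, normal approximation with
  tie correction otherwise; significance at p < 0.05.
* Age bins are integer bins <31, 31–40, 41–50, 51–60, 61–70, >70.
* Cardiovascular-risk quadrants use the cholesterol ratio
  (total/HDL cholesterol) against 4 and fasting glucose against 5 mmol/L,
  strict inequality on the high side (> 4, > 5), complements ≤; rows with
  nonpositive HDL are excluded with a counted warning. The full 2×2 of
  quadrants is always reported, empty cells with n = 0.
* Marker–age association uses the biweight midcorrelation
  (median-centring, Tukey biweights with the 9-MAD cutoff), implemented
  here from the standard definition and tested against an independent
  loop-coded oracle; it errors on zero-MAD inputs rather than returning a
  number.

## Permutation importance and partial dependence

Permutation feature importance reports the performance drop (MAE increase
for regression; F1 or accuracy decrease for classification) when one
feature column is permuted, over 10 seeded repeats, signed so that larger
always means more important. Partial dependence forces one feature across
a grid ({0, 1} exactly, for binary features) and averages model
predictions over the background rows.

**A direction the synthetic world cannot reproduce.** On real data, the
original analysis reports that predicted age *increases* with smoking
status as an input. In this generator that direction is unattainable, and
the package documents the test that pins this down as an expected failure
rather than weakening it: markers here encode *accelerated* biological
age, so two subjects with identical markers but different smoking status
differ in the other direction — the smoker must be chronologically
younger to look this old — and any well-fitted regressor learns a negative
smoking adjustment. The empirical positive dependence plausibly reflects
survivorship (smokers who reach old age are a selected, healthier group),
a mechanism deliberately excluded from the generator. Permutation
importance, which is direction-free, does recover that smoking matters.

## Known limitations

* The generator's marker magnitudes, slopes and missingness rates are
  conventions; no marker-level distributions from the original cohort are
  public, so only the *design* (sizes, balance, medians, missingness
  ranges) is emulated.
* The arbitrage-space construction and the knee selection rule are
  reproducible conventions standing in for undocumented choices.
* Reported headline numbers of the original study (MAE ≈ 5.7 y, R² ≈ 0.56,
  smoking F1 ≈ 0.67) are properties of private data and are intentionally
  not targets; the synthetic world is cleaner and the models
  correspondingly stronger.
* The Mann–Whitney p-values are per-cell and unadjusted; with 12 strata a
  multiplicity correction would be appropriate for confirmatory use.
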