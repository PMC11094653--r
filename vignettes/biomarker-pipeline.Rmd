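---
title: "Discovering a metabolomic biomarker of acute sleep deprivation"
author: "wakemark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering a metabolomic biomarker of acute sleep deprivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Prolonged wakefulness changes the plasma metabolome in two distinct ways:
some metabolites drift monotonically with accumulated time since wake (TSW)
— the signature of the sleep homeostat — while others oscillate with the
~24-hour circadian clock regardless of how long a person has been awake. A
deployable blood test for acute sleep deprivation should ride the first kind
of signal and avoid the second, because samples in the field arrive at
arbitrary circadian phases.

`wakemark` implements a complete discovery-and-validation pipeline for such
a biomarker from untargeted LC-MS feature tables collected under
constant-routine protocols:

1. **Preprocess** relative peak areas into analysis views.
2. **Characterize** every feature's linear (homeostatic) and 24-h cosinor
   (circadian) trends, per participant and at the group level.
3. **Filter** features a priori: significantly and consistently linear in a
   majority of individuals and at the group level, and rhythmic in no more
   than a quarter of individuals.
4. **Select** a minimal candidate panel with three-stage random-forest
   variable selection and cross-model consensus.
5. **Model** well-rested (WR, TSW 0–16 h) versus sleep-deprived (SD, TSW
   24–38 h) classification and TSW regression, validated strictly on a
   held-out, independently collected experiment.
6. **Validate recovery**: candidates must stop drifting (or reverse) after a
   night of sleep in a matched-control protocol, and must not be explained
   by meal timing.

Because the motivating study's raw data are not publicly deposited, the
package ships a first-class synthetic-data generator that emulates the study
design, so every stage is testable end to end against planted ground truth.

## The models

**Linear trend.** For feature $y$ sampled at times-since-wake $t$:
$y = \beta_0 + \beta_1 t + \varepsilon$, with the exact t-test for
$\beta_1 = 0$. The slope sign is the feature's direction.

**Cosinor.** $y = M + A\cos\!\big(\tfrac{2\pi (t - \phi)}{24}\big) + \varepsilon$,
fitted linearly via $\beta_c \cos(2\pi t/24) + \beta_s \sin(2\pi t/24)$ with
$A = \sqrt{\beta_c^2+\beta_s^2}$, acrophase
$\phi = \tfrac{24}{2\pi}\,\mathrm{atan2}(\beta_s,\beta_c)$, and the joint
F-test of $\beta_c = \beta_s = 0$. The period is fixed at 24 h.

A numerical caveat that shaped the design: over the 2–38 h sampling window
(1.5 cycles) an unmodeled linear trend projects substantially onto the
cos/sin regressors — the amplitude bias is roughly $3.3 \times$ the slope
in these units. The default `fit_cosinor()` is the plain cosinor (separate
models, matching common practice in this literature); the
`linear_covariate = TRUE` option fits the joint model
$y = \beta_0 + \beta_1 t + \beta_c\cos + \beta_s\sin + \varepsilon$, which
removes that bias exactly on noiseless input, and is what our fit-recovery
tests use for mixed (trend + rhythm) features. For the *filter* this bias is
conservative: drifting features look, if anything, more rhythmic, and must
still clear the cyclicity exclusion.

**Multiplicity.** Benjamini–Hochberg FDR across features, separately per
(level, model family). The a priori filter itself uses raw per-test
$p < 0.05$, as a knowledge-based screen rather than an inferential claim;
the characterization's FDR is deliberately not reused there.

**Hold-out metrics.** Accuracy is trace/total of the confusion matrix with
a Clopper–Pearson exact binomial 95% CI (lower bound $(\alpha/2)^{1/n}$ at
$x=n$); training accuracy is $1 -$ OOB error on the same footing. ROC scores
are the fraction of trees voting SD; AUC is the trapezoid/Mann–Whitney value
with a DeLong-type asymptotic CI (cross-checked against pROC in the tests).
Test-set $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ is signed (negative allowed).
Conditional rates are reported with explicit numerator/denominator
definitions (`rate_true_wr = tn/(tn+fp)` etc.) because
sensitivity/specificity/PPV/NPV labels are used inconsistently across
reports of this design.

## The a priori filter

A feature passes iff, in the *training* experiment only:

* the fraction of participants with a significant linear trend whose slope
  sign agrees with the majority sign is **strictly greater than 0.50**;
* the group-level (pooled) linear fit is significant with the same sign;
* the fraction of participants with a significant cosinor amplitude is
  **not greater than 0.25** (strictly more than a quarter excludes).

"Monotonic" is operationalized as cross-participant direction consensus.
Both boundary semantics mirror the "more than 50%" / "more than 25%"
phrasing and are configurable.

## Three-stage variable selection

Stage parameters default to `ntree_thres = 300, nfor_thres = 40,
ntree_interp = 100, nfor_interp = 30, ntree_pred = 100, nfor_pred = 10`.

1. **Thresholding** — raw permutation importance (mean decrease in accuracy
   for classification, increase in MSE for regression) averaged over
   `nfor_thres` forests; an unlimited-depth CART of the importance *sd*
   against rank gives a piecewise-constant curve whose minimum is the
   threshold; variables with mean importance at or above it survive. Ties
   are broken by first appearance.
2. **Interpretation** — nested models grown in importance order; the
   smallest model whose mean OOB error is within one sd (at the minimizer)
   of the global minimum is kept. This stage retains relevant-but-redundant
   variables, which is what a biomarker consensus wants.
3. **Prediction** — stepwise inclusion; a variable enters only if it lowers
   mean OOB error by more than the mean absolute first difference of OOB
   errors among the stage-2-rejected models. The first variable is judged
   against the null model (majority-class error rate, or the variance of
   the target), so an all-noise input can legitimately return an empty set;
   this differs from implementations that always seat the top variable, and
   makes the degenerate case honest.

Candidates are variables present in the interpretation sets of a **strict
majority** of the (task × view) selection runs, ranked by frequency then
mean importance, with a top-$k$ fallback (default 5) when no variable
reaches a majority — on easy synthetic data a single near-perfect feature
can collapse classification interpretation sets to size 1, which makes the
fallback the common path there.

## Random-forest models

All biomarker models use `mtry = 3` (capped at the number of predictors),
`ntree = 500`, terminal node size 1 (classification) / 5 (regression), and
forest seed 123; the seed governs forest construction only, never the
simulated data. Time bins are closed intervals; with bi-hourly sampling the
boundary only matters at 16 and 24 h. The threshold scan folds 18/20/22-h
samples stepwise into either condition; the combination scan fits all
$\sum_{k\ge 2}\binom{5}{k} = 26$ candidate subsets and tests each test
accuracy against the no-information rate (majority class of the evaluated
test subset) with a one-sided exact binomial test, Bonferroni-corrected
across combinations.

## Recovery after sleep

Candidate z-scores in 4-h blocks before/after the habitual sleep interval
are contrasted with `value ~ period + (1 | participant)` via lme4, with
Satterthwaite degrees of freedom (lmerTest) and BH-FDR across all
(metabolite × protocol) tests within a design; a singular fit falls back to
a paired t-test on participant means. Two designs are built in:
clock-matched (TSW 2–6 vs 26–30 h; control day-2 vs day-3 at TSW 2–6 h) and
evening/morning (TSW 12–16 vs 26–30 h; control day-2 12–16 h vs day-3
2–6 h). Meal-timing robustness compares a well-rested day across feeding
regimes with `value ~ tsw * protocol + (1 | participant)`; both tables must
be z-scored across the compared day only, because z-scoring across designs
of different length rescales slopes incommensurately and manufactures a
spurious interaction. The control table's z-scores span the participant's whole stay (the study
leaves this unstated; the per-day alternative differs only by a per-day
scale).

## The synthetic study

`make_feature_panel()` draws a reusable panel of feature "biologies" shared
by all experiments; `generate_sleep_dep_experiment()` and
`generate_matched_control()` realize protocols from it. Intensity model per
sample:

$$y = B_f e^{u_p} + b_f\,\mathrm{tsw} + A_f \cos\!\big(\tfrac{2\pi(\mathrm{clock}-\phi_f)}{24}\big) + \varepsilon,\qquad \varepsilon \sim N(0, \sigma_f^2),$$

floored at zero. The homeostatic term runs on time-since-wake (it resets at
sleep in the matched control); the circadian term runs on clock time and is
participant-independent (constant-routine protocols align wake times).

Defaults, chosen once as realistic for HILIC LC-MS plasma data and then
left alone:

| parameter | default | rationale |
|---|---|---|
| baseline $B_f$ | log-normal, log-mean 10, log-sd 0.5 | LC-MS dynamic range |
| class mix | 2% linear / 25% circadian / 5% mixed / 68% null | echoes the observed trend-category proportions |
| slope $b_f$ | ±(1–3)% of $B_f$ per hour | detectable but honest per-participant effect |
| amplitude $A_f$ | (10–30)% of $B_f$ | typical rhythmic fractions |
| noise $\sigma_f$ | 5% of $B_f$ | technical + residual biological CV |
| participant offset $u_p$ | $N(0, 0.3^2)$ | between-participant baseline spread |
| censoring | per-feature quantile; 90% of features at $q \le 0.12$, 10% at $q \in [0.22, 0.40]$ | yields a realistic minority of features failing a 20% zero cutoff |
| missingness | fixed count `round(rate × scheduled)`, completely at random | reproduces reported sample counts exactly (e.g. 218 of 228) |

What the generator does **not** emulate: chromatographic drift, batch and
run-order effects beyond a scalar per-experiment factor, isotopes/adducts,
heavy-tailed noise, correlated feature blocks, participant-specific
circadian phase, and non-linear homeostatic saturation (real candidates
plateaued beyond ~20 h awake). Passing tests therefore demonstrate that the
*pipeline logic* recovers planted structure at study-realistic sizes and
noise — not that real plasma data would behave this gently; hold-out
accuracies near 100% on synthetic data are expected and say nothing about
field performance.

## Numerical choices and degenerate inputs

* Zeros always mean "below detection", never true zero; imputation draws
  from a per-feature normal truncated to (0, observed minimum), with
  (μ, σ) recovered by quantile matching against the censoring fraction — a
  deliberate, seeded simplification of quantile-regression left-censored
  imputation; `half_min` is the deterministic alternative. An entirely
  censored feature falls back to the global minimum rule with a warning.
* The median-normalization reference is the median of per-sample medians
  (the convention is unstated in this literature; alternatives differ by a
  global scalar that cancels in all rank- and z-based downstream steps).
* Z-scoring uses the n−1 sd; a constant series maps to 0 with a warning; a
  participant with one sample is an error naming the participant.
* A noiseless flat series gets linear p = 1 (not NaN); a noiseless perfect
  trend gets p = 0.
* The zero-fraction filter uses strict ">" at 0.20, and is idempotent, as is
  median normalization (tolerance 1e-9).
* The empirical ROC always contains the predict-nothing endpoint, so a
  specificity target is formally always attainable (sensitivity 0 in the
  worst case); `sp_targeted_sensitivity()` maximizes sensitivity subject to
  the target.

## Problem sizes used in tests and scripts

The shipped tests and the acceptance script run the pipeline at the study's
own design sizes — 12 + 11 participants, 19 bi-hourly samples each, 1000
features (20 linear / 50 circadian / 30 mixed / 900 null for planted-truth
property checks), 5-participant matched control — and a 20-variable
selection problem for the three-stage procedure at its full stage
parameters. The numbered `analysis/` drivers use a 25%-circadian panel to
make the characterization step's contingency comparison non-trivial. All
fit comfortably on a single CPU.

## Known limitations

* Group-level fits are pooled OLS; the original analysis used moderated
  (empirical-Bayes) statistics for group characterization. With ~200
  samples per experiment, moderation changes little, but small studies
  would warrant it.
* The three-stage selection follows the published procedure's structure;
  micro-choices the original leaves open (CART depth for the sd curve,
  tie-breaking, the first-variable rule at the prediction stage) are fixed
  here as documented above.
* The recovery mixed model assumes a random intercept only; random slopes
  are unidentifiable in 4-h blocks.
* Regression of TSW inherits the biomarker's saturation behavior in real
  data; the synthetic generator is linear in TSW, so synthetic regression
  results are optimistic by construction.
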