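---
title: "Labeling sepsis onset and evaluating real-time risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Labeling sepsis onset and evaluating real-time risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Electronic health records contain no ground-truth label for sepsis. The
sepsis-III consensus operationalises sepsis as an acute rise of two or more
points in the SOFA organ-dysfunction score in the presence of suspected
infection, but it does not pin down an *onset time*. Retrospective studies
therefore reconstruct onset from two proxies — the time clinicians showed
suspicion of infection (antibiotics plus cultures) and the time organ
function deteriorated — and different reconstructions yield different
prediction targets, different analysis cohorts, and materially different
measured model performance. `sepsislab` implements the complete
reconstruction and evaluation pipeline so that every rule is explicit,
tested, and swappable: the suspicion pairing rules, hourly SOFA scoring,
three competing onset definitions, cohort exclusions, patient-hour
labeling, feature construction (including path signatures), three risk
scorers, and patient-hour AUROC evaluation with patient-level bootstrap
intervals. A synthetic ICU generator with recorded ground truth makes the
whole chain verifiable without access to credentialed clinical data.

## Suspicion of infection

Doses of the same antibiotic form a *course* while consecutive doses are at
most 48 hours apart; only the first time of each course is a candidate
antibiotic start. A candidate start `s` qualifies only if at least two
doses of *any* antibiotic fall in `[s, s + 96]` hours, which removes
one-off prophylactic doses. A qualifying start pairs with a culture draw
when the culture follows the antibiotic by at most 24 hours, or precedes it
by at most 72 hours. The suspicion time of a pair is its earlier member,
and a stay's `t_suspicion` is the earliest over all valid pairs. All
boundaries are inclusive, and simultaneous events are treated as
antibiotic-first; both choices are arbitrary at measure-zero boundaries and
are fixed for determinism. By default only blood cultures count; the
`include_other_specimens` flag widens the pairing to all specimen types
(the "other cultures" sensitivity variant).

## Hourly SOFA and the deterioration time

Observations are floored onto an hourly grid (hour `h` covers `[h, h+1)`,
ties resolved by the latest observation in the hour) and forward-filled
with no staleness limit; a variable contributes zero to its subscore before
its first observation, the conservative convention of sepsis-III
reimplementations. Urine output is summed per hour and scored against the
standard 24-hour bands only once 24 hours of data exist, so no spurious
oliguria scores arise early in a stay. The six subscores (respiration,
coagulation, liver, cardiovascular, CNS, renal) follow the standard
published thresholds; respiration scores of 3-4 require the ventilation
flag, and the cardiovascular subscore combines hypotension (MAP < 70) with
dopamine/norepinephrine dose bands.

`t_sofa` is found inside a *SOFA window* `{x, y}` — from `x` hours before
to `y` hours after `t_suspicion`: the trace is restricted to the window
(clipped to the stay), the *initial value* is the total at the first
restricted hour, and `t_sofa` is the earliest hour at which the total
reaches the initial value plus two. Which hour anchors the "initial value"
is genuinely underdetermined; we use the window start (configurable via the
code path) because it reads the rise as occurring within the window
depicted around the suspicion time. Note one consequence, verified by the
property tests: enlarging `y` at fixed `x` can only add or advance
detections, whereas enlarging `x` can in principle shift the baseline.

## Onset definitions, exclusions, split, labels

With both events in hand, three onset definitions compete: `H1` places
onset at `t_sofa` (organ dysfunction), `H2` at `t_suspicion`, and `H3` at
the earlier of the two; all three require both events, and
`H3 = min(H1, H2)` by construction. A stay with a suspicion time but no
in-window SOFA rise is treated as a control.

Exclusions fire in a fixed order so that flow-diagram counts are
reproducible: pre-ICU antibiotics; excluded care unit (cardiothoracic
surgical by default); elective surgical admission; length of stay outside
[4, 480] hours; no vital-sign data at all; onset within 4 hours of
admission; and finally one stay per patient (earliest kept). The *strict*
variant applies the early-onset rule using the H3 onset regardless of the
cohort's own definition, so H1/H2 cohorts share H3's (strictest)
exclusions — for H3 itself it is a no-op. The train/test split (85/15 by
default) is stratified on sex, age quartile, length-of-stay quartile and
ever-ventilated status and is assigned *before* exclusions; per-stratum
train counts use stochastic rounding, keeping every stratum within one
patient of the target fraction without starving the test set in small
strata, and singleton strata go to train with a warning.

For the real-time task each in-cohort stay contributes patient-hours:
non-septic stays every in-stay hour labelled 0; septic stays only hours
strictly before onset, with hour `h` positive exactly when onset falls in
the half-open lookahead `(h, h + T]` (horizon `T = 6` h by default). Onset
is floored to the grid first, which makes the positive count per septic
stay exactly `min(T, onset)` — a closed form the tests assert. Training
only on pre-onset hours keeps the scorers predictive rather than
re-detecting the label definition.

## Features

The default design matrix has 113 columns: 38 raw predictors (34
forward-filled clinical time series plus age, sex and the two admission
clocks) and 75 derived ones (rolling max/min/mean over 8 h for seven
vitals, 8-h raw-measurement counts for ten variables, 8-h deltas for heart
rate and MAP, and depth-2 time-augmented path signatures of seven vitals).
Hours before a variable's first observation are filled with a fixed
per-variable reference value so every entry is finite. The derived set is a
configurable default in the documented style of published sepsis
early-warning pipelines, not a canonical list; `feature_spec()` replaces it
wholesale.

The *path signature* of a piecewise-linear path is the graded sequence of
its iterated integrals; level 1 is the total increment, level 2 encodes
ordered co-movement (e.g. "did heart rate rise before pressure fell"), and
the whole object is invariant to time reparameterisation unless a time
channel is added — which we do, making the features sensitive to pacing.
`signature_transform()` computes exact signatures of arbitrary depth via
Chen's identity (segment signatures are tensor exponentials); the rolling
per-hour features use the depth-2 closed form for a 2-channel (time,
value) path, which the tests verify against `signature_transform()` and a
direct iterated-integration oracle. Windows truncated to a single point
yield zero vectors. End-tidal CO2 is deliberately absent from the
vocabulary.

## Risk scorers

All three scorers consume the same patient-hour matrix and emit a risk in
(0, 1), higher meaning sepsis onset more likely within `T` hours.

* **Gradient-boosted trees** (`"gbm"`): xgboost with the histogram method,
  single-threaded, no row/column subsampling, so fits are bit-reproducible.
  Defaults: depth 3, 100 rounds, learning rate 0.1, minimum child weight
  10.
* **LSTM** (`"lstm"`): a single-layer LSTM (16 units) over each stay's
  standardized hourly sequence with a per-hour sigmoid read-out,
  implemented in vectorised base R inside the package and trained with
  backpropagation through time and Adam (learning rate 0.01) on mini
  batches of 64 stays for 15 epochs. Single-threaded R arithmetic makes a
  fixed seed reproduce fits exactly; we still document a 1e-10 tolerance
  for cross-platform floating-point variation.
* **Proportional-hazards horizon risk** (`"coxphm"`): a Cox model with
  time-varying covariates on counting-process rows `(h, h+1]`, fitted with
  a ridge penalty (glmnet, lambda 0.03, escalated fivefold on divergence)
  because the patient-hour design is collinear and near-separable. The
  Breslow baseline cumulative hazard is computed on the unit intervals and
  linearly interpolated (anchored at the origin, extrapolated at the mean
  observed rate) so the horizon increment is strictly positive; the score
  is `r(t) = 1 - exp(-(H0(t+T) - H0(t)) exp(beta x_t))`. The horizon-risk
  formulation is our interpretation of a survival-analysis scorer
  commensurate with the classifier outputs; the interface allows
  substitution.

Hyperparameters can be tuned with `tune_cv()` — patient-grouped 5-fold
cross-validation selecting on mean fold AUROC, refitting the winner on the
full training set — though the experiment driver uses the fixed defaults
unless asked. Risk scores convert to binary alerts at the largest threshold
achieving 85% sensitivity on training patient-hours (an order statistic of
the positive-row scores).

## Evaluation

AUROC is computed pooled over patient-hours (not averaged per patient) via
the rank statistic with ties counted one half. Confidence intervals are
percentile bootstrap over 100 resamples drawn at the *patient* level, which
respects within-stay correlation; resamples on which the metric is
undefined are redrawn and counted. Percentile rather than BCa intervals are
used because 100 resamples are too few for stable BCa corrections.
Sensitivity, specificity and accuracy are reported at the calibrated
threshold on test patient-hours. `run_experiment()` crosses definitions,
models, windows, horizons and exclusion variants, emits one report per
cell, and flags the headline pitfall — when the best model under the worst
definition underperforms the worst model under the best definition, naive
cross-paper comparison would invert the model ranking.

## The synthetic cohort

The generator emulates the statistical shape the pipeline assumes, with
ground truth recorded for every latent quantity. Each septic stay draws an
infection time tau; an inflammatory prodrome (heart rate, respiratory
rate, temperature, SpO2, white cells, lactate) ramps from tau over 12 h,
and organ dysfunction (MAP, platelets, bilirubin, creatinine, GCS,
PaO2/FiO2, urine output, pressors, ventilation) follows after a 4-10 h
organ lag with an 8 h ramp. Clinician response trails the visible
prodrome: the first antibiotic dose about 8 h and the first culture about
7 h after tau, so suspicion pairs form around the prodrome and the
pre-onset hours that the horizon labels mark as positive genuinely carry
early signal — as in real cohorts, where deterioration precedes the
recorded response. Non-septic stays receive only background events —
one-off antibiotic doses, which can never satisfy the two-dose
qualification, and stand-alone cultures — so with the septic fraction at
zero the pipeline provably produces zero sepsis-positive stays, while the
pairing rules' rejection paths still get exercised. Sampling rates are
realistic (vitals hourly, chemistry every 12-24 h), values are clipped to
physiological bounds, and 5% of scheduled measurements are dropped at
random.

What the generator does *not* emulate: real MIMIC-style distributions and
their heavy tails, informative/acuity-driven sampling, comorbidity
structure, multiple infection episodes, pre-ICU trajectories, or
documentation artifacts. Passing tests therefore demonstrate that the
labeling rules, metrics and training loops are implemented correctly and
that the scorers can recover a planted signal — not that any score
transfers to real patients, and not a reproduction of clinical AUROC
values, which require the credentialed source data.

## Numerical choices and problem sizes

Determinism is treated as a feature throughout: every stochastic step
derives a child seed from a caller-supplied seed, the generator restores
the caller's RNG state, the split and bootstrap are seed-stable, and the
pipeline driver caches stages by semantic content hash (JSON-serialised
configuration), so reruns are no-ops and deleting an intermediate
recomputes only downstream stages. The test suite and the acceptance
script exercise the full chain on a 500-patient cohort (septic fraction
0.3, SOFA window {24, 12}, horizon 6 h, nine model-by-definition cells,
100 bootstrap resamples), sizes chosen so a complete desk-scale run
finishes in minutes on one core; oracle checks run on 500-1000 randomised
micro-instances per rule.

## Known limitations

Forward-fill is the only imputation offered, matching the target protocol;
staleness-aware or model-based imputation is out of scope. The "initial
value" anchoring of the SOFA window, the exclusion order, and the exact
derived-feature list are documented package decisions where the field's
practice is heterogeneous. The LSTM is deliberately small and CPU-bound;
it demonstrates the sequence-model route, not a tuned architecture. The
horizon-risk CoxPHM is one defensible reading of a survival scorer for
this task among several.
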