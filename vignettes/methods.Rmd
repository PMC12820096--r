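---
title: "Methods: within-trial cost-effectiveness and budget impact of reduced mammographic surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-trial cost-effectiveness and budget impact of reduced mammographic surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ceasurv` implements a within-trial economic evaluation comparing annual
with less frequent surveillance mammography in people treated surgically
for breast cancer, together with a national budget-impact calculator. This
vignette is the package's own account of the models, the choices behind
them, and what the test evidence does and does not establish.

## The estimation problem

Two arms are compared over a 5-year follow-up window: annual surveillance
mammograms versus 2-yearly mammograms after breast-conserving surgery and
3-yearly after mastectomy. The estimands are the incremental per-patient
cost $\Delta C$ (GBP), the incremental quality-adjusted life years
$\Delta Q$, and the incremental net monetary benefit

$$\mathrm{INMB}(\lambda) = \lambda\,\Delta Q - \Delta C$$

at willingness-to-pay $\lambda$, with £20,000/QALY as the primary
threshold. The probability that the reduced-frequency policy is
cost-effective, as a function of $\lambda$, is the cost-effectiveness
acceptability curve (CEAC), estimated as the fraction of bootstrap draws
with strictly positive INMB.

## Data structure and the synthetic generator

Questionnaires (EQ-5D-5L and most cost categories) are collected only at
mammogram visits, so the less-frequent arm is observed at far fewer
timepoints *by design*; hospital-record costs (admitted and outpatient
care) are observed for everyone except a configurable fraction at the
final timepoint. The package treats the analysis window as visit
timepoints 4–8, nominal years 1–5 from randomisation, with the
randomisation-time mammogram at timepoint 3. Under the stated schedules
the less-frequent arm is therefore observed at timepoints 5 and 7
(conservation) or 6 (mastectomy), plus any patient-requested unscheduled
mammograms.

Because patient-level trial data of this kind are not freely
redistributable, the generator (`sim_config()`, `generate_trial()`,
`apply_design_missingness()`, `apply_dropout()`) is a first-class, tested
module. Its defaults encode the study conditions the analysis assumes:

* **Arms and strata.** Equal arms; conservation surgery 80%;
  age bands 53–55 (8%), 56–75, over 75 (9%); disease type, hormone
  therapy and ER status as binary strata with plausible prevalences.
* **Costs.** Each of 13 non-mammogram categories is a per-visit
  zero-inflated lognormal, parameterised by the arm-level 5-year mean and
  SD of the reference summary tables shipped in `inst/extdata`, with a
  patient-level multiplicative lognormal effect (log-SD 0.5) inducing
  within-patient correlation. Categories whose reference median is £0
  carry heavy zero inflation. Mammogram costs are not drawn: they are
  visit counts from the schedule (plus requests) times the unit cost, so
  the annual-arm 5-visit median of 5 × £115.25 = £576.25 and the
  less-frequent 2-visit £230.50 arise structurally.
* **Planted effects.** `true_effects` (defaults $\Delta C = -544$,
  $\Delta Q = -0.02$) are enforced analytically: the four non-mammogram
  healthcare category differences are shifted equally so that, together
  with the schedule-implied expected mammogram difference, the implied
  healthcare $\Delta C$ equals the target; the per-visit utility offset is
  $\Delta Q$ divided by the horizon. `configured_effects()` returns these
  implied truths (exact when the death hazard is zero; slightly attenuated
  otherwise because both arms lose visits to death).
* **Utilities.** A mixture of a ceiling mass at 1 (20%) and a scaled Beta
  on $(-0.594, 1)$ — the floor of the UK 3L value-set scale — with
  per-visit means drifting downward (0.784 to 0.739 over timepoints 4–8)
  and a patient-level shift on the Beta mean. Generated utilities are
  quantised to the nearest profile of the value set, so every index in
  the data corresponds to an actual EQ-5D-5L profile.
* **Missingness calibration.** Dropout (questionnaire non-return) rises
  linearly from 0.10 to 0.50 over timepoints 4–8 and unscheduled-request
  probabilities are (0.067, 0.01, 0, 0.01, 0.02); these were solved once,
  analytically, so that combined design-plus-dropout missingness in the
  less-frequent arm is ≈94%, ≈86% and ≈99% at timepoints 4, 6 and 8 — the
  pattern the analysed trial reported — and were not revisited afterwards.
* **Survival.** Exponential death hazard 0.0113/year per arm
  (≈94.5% 5-year survival); recurrence onset hazard 0.01/year.

What the generator does *not* emulate: calendar-time effects (timepoint
dates varying by recruitment), informative (MNAR) non-return, correlation
between cost categories beyond the patient effect, recurrence-driven cost
spikes, and HES coding artefacts. Tests passing on synthetic data
therefore establish the *estimators'* correctness under a known
data-generating process, not robustness to every feature of real trial
data.

## Health outcomes

EQ-5D-5L profiles map to utility indices by pure table lookup
(`crosswalk_index()`). The published 5L-to-3L crosswalk is licensed and
not shipped; `synthetic_value_set()` builds a complete synthetic table
over all 3,125 profiles with an additive monotone decrement model anchored
at 1.0 for `11111` and −0.594 for `55555`. Analyses of real data should
load the licensed table with `read_value_set()`.

QALYs are the area under the utility-time curve (`qaly_auc()`), with
trapezoidal interpolation between visits. The death convention is not
dictated by standard practice alone, so both are implemented: linear
decline to zero at death (default) and last-observation-carried-forward
(`death_rule = "locf"`). Censored patients contribute up to their last
observation; no extrapolation. Trajectories are anchored at randomisation
by carrying the first observed utility back to time 0
(`anchor = "carry_back"`), so a constant utility of 1 over the 5-year
horizon yields 5 QALYs; `anchor = "first_obs"` starts integration at the
first visit instead. Patients who die before their first visit (rare,
≈1%) are anchored at the arm-mean first-visit utility. No discounting is
applied within the trial window (a rate hook exists, default 0).

## Costing

Fourteen cost categories follow the trial's tabulation: five healthcare
(community-based health/social care, prescribed medications, admitted
patient care, outpatient care, mammograms) and nine societal
(non-prescribed medications, private/self-funded treatment, other
expenses, travel, parking, time off work, incapacity benefits, unpaid
informal care, friends'/family time off work). `assemble_perspective()`
sums the five or all fourteen. Unit costs and inflation indices are
editable CSV resources; the shipped mammogram unit cost is £115.25
(2023 screening-mammogram cost) with £33/£272 sensitivity bounds, and the
shipped NHSCII/CPI series are illustrative placeholders, not the national
compendia. Currency is kept as decimal GBP throughout and rounded only
for display.

## Multiple imputation

`impute()` runs chained equations separately by arm (the imputation of
one arm never reads the other's rows), with defaults of m = 25 completed
datasets and up to 20 iterations. Per-variable conditional models regress
each incomplete variable on the stratification variables, time,
recurrence status, mammogram counts, the allowed same-visit variables,
and patient-level means of observed values. The predictor hierarchy is:
EQ-5D and healthcare costs predict everything; societal costs predict
only societal costs. The visit sequence follows that hierarchy (EQ-5D,
then healthcare costs, then societal).

The repeated-measures ("two-level") structure is approximated by the
cluster-mean predictors; an exact random-intercept normal backend was
considered and a log-scale normal draw (`method = "norm"`) is provided as
the alternative engine. The default engine is type-1 predictive mean
matching with k = 5 donors: regression parameters are drawn from their
approximate posterior, missing cases are matched to the k observed cases
nearest in fitted value, and one donor's *observed* value is imputed —
hence imputed costs are automatically non-negative and respect the
zero-inflation. Skewed costs enter their regressions as
$\log(x + \delta)$ with $\delta$ = £0.01. Missing-by-design and
missing-by-dropout cells are treated identically, as the analysed design
draws no distinction. `diagnostics()` reports observed-versus-imputed
summaries, chain-mean traces and fraction-of-missing-information
estimates.

## Estimation and uncertainty

Patient-level totals (cost under the chosen perspective; QALYs) are
modelled as a two-equation system on the arm indicator and the five
stratification covariates, estimated by feasible GLS (`fit_sur()`):
per-equation OLS, residual cross-equation covariance, then the joint
solve. With identical regressors in both equations the GLS solution
equals per-equation OLS (Kruskal's theorem); the test suite uses that
equivalence as an oracle, and the residual covariance still measures the
cost–QALY correlation. Patient-level totals are the default unit of
analysis; the repeated-measures alternative was considered and rejected
as the default because the estimands are per-patient 5-year totals.

Uncertainty comes from non-parametric bootstrap (`bootstrap_cea()`):
within each imputed dataset, patients are resampled with replacement
*stratified by arm* (so no replicate degenerates to a single arm — a
design choice where the analysed method was silent) and the system is
refitted; the default 25 × 5,000 draws are pooled into one empirical
distribution for the CE plane, percentile 95% intervals, CEAC and INMB.
Rubin's-rules pooling of the per-imputation point estimates is reported
alongside as the deterministic summary, since bootstrap-with-MI pooling
conventions differ. Ties at INMB exactly 0 count as *not* cost-effective
(a measure-zero convention). The WTP grid is £0–£50,000 in £500 steps,
always containing £20,000 and £30,000.

Secondary analyses re-run the pipeline: societal perspective (14
categories), 6-year horizon (`timepoints = 4:9`), outpatient-cost
exclusion (`exclude = "outpatient"`), subgroup analyses by stratification
variable (subgroup covariate dropped from the design; subgroups under a
configurable floor are flagged, not estimated), and the mammogram
unit-cost sensitivity analysis over £33/£115.25/£272.

## Budget impact

`bia_run()` is a deterministic expectation-based cohort calculator over a
6-year horizon (2024–2029). Patients enter at diagnosis, receive annual
surveillance in years 1–3 since diagnosis, reduced-frequency surveillance
(0.5 mammograms/year after conservation, 1/3 after mastectomy — steady-
state rates rather than calendar-exact schedules, matching the model's
annual granularity) from year 4, and exit after completing the 5-year
reduced-surveillance window. Cohorts are thinned annually by
survival × (1 − attrition); fractional persons are carried without
rounding. Savings are mammograms avoided × unit cost, with no
discounting. Because "population contributing to savings" can be read as
patient-years or unique patients, both tallies are emitted. One-way DSA
recomputes cumulative savings at low/high bounds of one parameter at a
time; unit-cost scenarios rescale savings linearly.

The shipped population inputs (50,000 entrants/year, survival 0.95,
attrition 0.05, steady-state initial prevalence) are clearly-marked
synthetic placeholders of England-scale magnitude; national projections
require registry-derived inputs via `read_bia_inputs()`.

## Numerical choices and degenerate inputs

* Rank-deficient regression designs abort naming the collinear columns;
  constant factors (e.g. the subgroup variable within its own subgroup)
  are dropped automatically from imputation designs.
* A (near-)singular residual covariance in the two-equation system (e.g.
  constant outcomes) falls back to the OLS solution, which solves the GLS
  system in that case.
* PMM donor ties are resolved by the sort order of fitted values; the
  donor among the k nearest is chosen uniformly.
* An imputable variable with 100% missingness in an arm has no donors and
  fails with the variable named.
* All randomness flows from explicit integer seeds; generation,
  imputation and bootstrap each restore the caller's RNG state.

## Problem sizes used in the shipped checks

The test suite exercises the statistically demanding properties at sizes
chosen to make Monte-Carlo error small relative to the assertions while
keeping a full run to a few minutes: planted-effect recovery at 10,000
patients per arm with m = 5 and B = 500; interval calibration over 200
trials of 250 patients per arm (B = 500, m = 5); MCAR recovery at 2,000
patients; large-sample generator calibration at 20,000 per arm. The
acceptance script runs the full pipeline at 2,000 patients per arm with
m = 5 and B = 500, and reports bootstrap-mean summaries.

## Known limitations

* The cluster-mean approximation to two-level imputation understates
  between-patient variance relative to a full random-intercept draw.
* The reference summary tables are post-imputation arm-level statistics;
  using them as generator parameters conflates observed and imputed
  variability — acceptable for testing estimators, not for inference
  about the original trial.
* Percentile intervals from pooled MI-bootstrap draws have no exact
  finite-sample guarantee; the calibration experiment checks them
  empirically at one design point.
* The budget-impact placeholders are not registry values; its outputs are
  methodologically, not numerically, meaningful until real inputs are
  supplied.
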