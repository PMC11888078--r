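---
title: "Trial-based cost-utility analysis with cuatrial: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-based cost-utility analysis with cuatrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuatrial)
```

# The analysis this package implements

`cuatrial` implements a within-trial cost-utility analysis (CUA) for a
two-arm randomized design of the kind used to evaluate unguided
internet-delivered CBT against a waitlist control in depression: five
assessment waves (baseline, post-treatment, and 3-, 6-, 12-month
follow-ups), SF-6D-derived health utilities, bottom-up direct medical
costs, productivity costs from weekly disability-scale reports, and a
control arm whose follow-up stops at the post-treatment wave for ethical
reasons (the waitlist then receives the intervention).

The estimand is the pair (ΔC, ΔE): the baseline-adjusted incremental cost
and incremental QALY of intervention versus control at a given horizon and
costing perspective, summarized as the ICUR ΔC/ΔE and as decision
quantities over a willingness-to-pay (WTP) grid.

## Outcomes

Utilities enter either directly or through an additive SF-6D tariff
(`utility_from_sf6d()`): utility = 1 − Σ decrements, anchored at 1 for
full health, with values below 0 (worse than death) admitted. The package
ships only a *toy* tariff (`toy_tariff()`, and
`inst/extdata/toy_sf6d_tariff.csv`) because country-specific value sets
are licensed tables; real analyses load one via `read_tariff()`.

QALYs use the trapezoidal area-under-the-curve rule over the assessment
grid (`qaly_auc()`). The default grid is `{0, 0.25, 0.50, 0.75, 1.25}`
years — the boundaries of the costing periods (three 3-month periods and a
final 6-month period). The post-treatment assessment is often labelled
"week 8"; we integrate on the costing grid because cumulative QALYs of
roughly 0.14 by post-treatment at utilities near 0.6 are only consistent
with a 0.25-year first interval. A week-8 grid
(`time_grid(c(0, 8/52, ...))`) is available for sensitivity analyses, and
the choice is a config parameter, not a constant.

## Costing

Three layers (`direct_cost()`, `indirect_cost()`, `total_cost()`):

* **Intervention cost**: a per-participant constant (default 545 CNY) in
  the intervention arm, 0 in the control arm.
* **Direct medical cost**: the exact sum of drug, treatment, and
  diagnostic/examination components per period (bottom-up costing).
* **Indirect cost**: human capital approach. Weekly lost/reduced
  productivity days scale linearly to the period and cap at the period
  length (`sds_to_days()`; the cap per week is configurable between 7
  calendar and 5 working days). A reduced day is valued at a fraction
  0.4298 of a lost day — the presenteeism weight established for
  mental-health populations.

Two deliberate parameterizations: the daily wage divides the monthly wage
by 21.75 working days (the usual payroll convention; the divisor is a
`wage_model()` field because "days × monthly wage" is dimensionally
incomplete), and the monthly wage itself has **no default** — it is a
locale- and year-specific input. Analyses in this package's scripts and
tests use 10,000 CNY/month, a round figure of the right magnitude for an
urban Chinese wage in 2022; with it, the generator's default
productivity-day rates reproduce the indirect-cost magnitudes the package
is calibrated to. All computation is in CNY; no discounting is applied at
horizons up to 15 months.

## Missing data

Dropout-missing utilities and period costs are imputed by chained
equations with predictive mean matching (`mice_pmm()`). Each variable is
regressed on age, gender, antidepressant use, arm, its baseline value,
and its adjacent (previous/next) assessments; a missing cell receives the
*observed* value of a donor whose predicted mean is closest to the
parameter-perturbed prediction, so imputations never leave the observed
support — the reason PMM suits zero-inflated, right-skewed costs.
Defaults: m = 5 completed datasets, donor pool k = 5, 10 chained cycles.
m = 5 follows the common finding that 3–5 imputations suffice for point
estimation; k = 5 and 10 cycles are standard chained-equation practice and
exposed in the API. Downstream estimates pool by Rubin's rules — see
`rubin_pool()` for the exact within/between decomposition and
degrees-of-freedom formula.

Design choices worth flagging:

* Imputation models include **arm as a predictor** rather than running
  separately by arm: with the control arm truncated, per-arm models would
  leave some equations with too few cases.
* **Structural missingness is not imputation's job.** Control waves after
  the truncation wave are flagged `structural` and skipped by the imputer;
  they are completed by the extrapolation module instead. Conflating the
  two would let donor matching invent control-arm follow-up from
  cross-sectional noise.
* Imputation operates on per-wave utilities and per-period direct and
  indirect costs — not on derived QALYs or totals — matching the declared
  predictor structure.

## Joint regression

`fit_sur()` estimates the two-equation system (total cost; QALY) by
one-step feasible GLS with the residual covariance computed with divisor
n. Costs are modelled on the raw currency scale because the quantity of
interest is a mean difference in currency. Covariates: treatment, the
outcome's own baseline (baseline cost for the cost equation, baseline
utility for the QALY equation), age in years (uncentred), and binary
gender and antidepressant-use indicators. With identical regressor sets
the FGLS solution collapses to per-equation least squares (a classical
equivalence we test); an iterated FGLS variant is available because the
literature rarely states which was used, and the two agree closely in
practice. The stacked solve is equilibrated by its diagonal because the
two blocks live on scales ~10^6 apart (currency² vs QALY²).

## Decision analysis

`bootstrap_ce()` resamples participants with replacement **within arm**
(arm sizes preserved) and refits the entire chain per replicate; for the
intention-to-treat sample that means re-imputing inside every replicate
with a reduced cycle count (`fast_cycles = 2`), i.e. bootstrap outer,
imputation inner. The alternative (pooling first, bootstrapping
residuals) was ruled out as it understates imputation uncertainty.
Replicate failures are redrawn; more than 1% failures aborts the run.

From the draws: `classify_plane()` reports quadrant percentages with
boundary draws (ΔE = 0 or ΔC = 0) assigned to the positive side — a
probability-zero event under continuous models, fixed for
reproducibility; `ceac()` reports P(NMB > 0) per threshold, which equals
P(ΔC < 0) at λ = 0 and tends to P(ΔE > 0) as λ → ∞ (the curve is a step
function of the draw set; the display grid is 200 points from 0 to
3× GDP); `icur_ci()` gives a percentile interval of draw-wise ratios
(type-7 quantiles) but warns and flags itself whenever draws span
quadrants, where ratio intervals are uninterpretable — NMB-based
reporting is preferred there. CEAC monotonicity in λ holds only when all
draws have ΔE > 0, and that is the only form the test suite asserts.

The WTP grid anchors at per-capita GDP (80,976 CNY) with multipliers 1,
1.5 (base case), and 3, per the national costing guideline.

## Control-arm extrapolation

For horizons beyond the truncation wave, `fit_trajectory()` fits, on the
intervention arm only, one linear model per outcome (utility, direct,
indirect) per transition: value at wave t on value at wave t−1, baseline
value, age, gender, antidepressant use. `extrapolate_control()` then
recursively fills control waves with mean predictions at the
individual level (individual-level rather than arm-mean recursion keeps
covariate adjustment meaningful downstream), clamping utilities at 1 and
costs at 0. Mean (deterministic) extrapolation is the base case; a
stochastic variant adds residual draws for uncertainty propagation.
Structurally flagged cells are always recomputed and never read — a
poisoning test verifies no leakage of withheld control data.

## The synthetic generator

`trial_config()`/`simulate_trial()` emulate the target trial's
structure: n = 244 at 1:1 permuted-block allocation; utilities as
censored-normal around per-arm per-wave means (defaults 0.52→0.61
intervention, 0.56→0.60 control, SD 0.22, floor −0.3) with a person-level
random effect (share 0.6 of variance) driving within-person correlation;
cost components as zero-inflated lognormals calibrated to the pre/post
resource-user fractions and means of the motivating trial (e.g. baseline
direct costs ≈6,600 vs ≈5,900 CNY); productivity days as overdispersed
binomials whose rates reproduce baseline indirect costs ≈22,200 vs
≈18,900 CNY at the 10,000 CNY wage; monotone discrete-time MAR dropout
(completion ≈73% intervention / ≈94.3% control at post-treatment, with
optional covariate-dependent hazards); and structural truncation of
control follow-up after the post-treatment wave. Follow-up-period cost
and productivity levels decline gently (factors ≈0.9/0.85/0.8), since
only a qualitative "declining trend" is reported per period. The
individual-level cost–utility correlation is not reported anywhere; the
generator exposes it (`cost_utility_correlation`, default 0) without
asserting it is the trial's truth.

What the generator does **not** emulate: symptom trajectories, course
usage, non-lognormal cost shapes (e.g. heaped charges), non-monotone
intermittent missingness, and any genuine treatment-by-covariate
interaction. Passing tests therefore demonstrate the *machinery* is
correct under the assumed data-generating class, not that the trial's
substantive conclusions transfer.

A calibration caveat: the generator matches printed *moments* (arm-wise
means, SDs, user fractions, completion rates). Those moments imply a raw
post-treatment societal cost difference near +5,000 CNY, and no
baseline-adjustment coefficient attainable under this data-generating
class turns that into the negative adjusted difference the motivating
analysis reported from patient-level data. The package reports what its
pipeline computes; headline patient-level results are not reproducible
from published summaries, which is precisely why the generator exists.

## Numerical and degenerate-input policy

* Missing utility at a grid point makes `qaly_auc()` reject — imputation
  or extrapolation happens upstream, never silently inside integration.
* ΔE = 0 in `icur()` yields a signed-infinite sentinel with a warning,
  never silent division.
* Identical arms in `group_compare()` (zero variance) return p = 1
  rather than erroring, so degenerate fixtures summarize cleanly.
* Rank-deficient SUR designs are rejected naming the collinear columns;
  imputation models prune structurally unavailable or constant
  predictors instead (those are expected under truncation).
* All stage seeds derive deterministically from one master seed; panels,
  imputation stacks, and bootstrap draw sets are byte-identical under
  identical configuration.

## Problem sizes used in the shipped experiments

Chosen as the package's own balance of Monte-Carlo precision against
runtime: parameter recovery uses 200 replicate trials (n = 244, 30% MAR,
m = 5) with moderate dispersion — utility SD 0.2 with person-effect share
0.7 and lognormal σ = 0.5 costs — so that the bias bands are several
Monte-Carlo standard errors wide; null calibration uses 200 replicates
with B = 200 bootstrap draws; extrapolation recovery uses 100 replicates;
`scripts/acceptance.R` runs the full base case with m = 5 and B = 1000.

## Known limitations

* One-step FGLS standard errors carry no small-sample degrees-of-freedom
  correction (divisor n), slightly optimistic at small n.
* The ICUR percentile interval is reported because some method must be;
  published ratio intervals are often far narrower than bootstrap clouds
  support, and the flagging behaviour exists for exactly that reason.
* No MNAR sensitivity analysis, no multilevel imputation, no gamma/GLM
  cost models, no EVPI, no discounting, and no modelled extrapolation
  beyond the trial horizon — all out of scope by design.
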