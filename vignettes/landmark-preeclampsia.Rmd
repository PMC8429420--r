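---
title: "Sequential landmark prediction of preeclampsia from routine antenatal data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential landmark prediction of preeclampsia from routine antenatal data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelandmark)
```

## The problem

Preeclampsia complicates 3–5% of pregnancies and remains a leading cause
of maternal and perinatal morbidity. Nulliparous women are at elevated
risk and offer no obstetric history to condition on, yet every antenatal
visit produces routinely collected measurements — systolic and diastolic
blood pressure, maternal weight, hemoglobin, capillary glucose, urine
dipstick protein and (from gestational week 24) symphysis-fundal height.
`pelandmark` implements a *sequentially updated* prediction procedure
that turns those serial measurements, together with twenty
first-visit covariates, into a preeclampsia risk that can be refreshed
at pre-specified gestational landmarks (completed weeks 24, 28, 32, 34
and 36), each time using only the information available by then and only
for women still predictable — not yet diagnosed and not yet delivered.

## The model, in three steps

**Step 1 — population mean trajectories.** For each continuous marker
$m$ the mean curve of the *non-preeclamptic* population is fitted with a
linear mixed model

$$y_{ij} = f_m(t_{ij}) + b_i + \varepsilon_{ij}, \qquad
  b_i \sim N(0, \sigma_b^2),\ \varepsilon_{ij} \sim N(0, \sigma^2),$$

where $t_{ij}$ is the gestational age in days at woman $i$'s visit $j$
and $f_m$ is a fixed cubic B-spline (boundary knots at days 42 and 310,
interior knots at weeks 16/24/32) — flexible enough for the
characteristic second-trimester dip of blood pressure and hemoglobin.
Symphysis-fundal height, observed only from week 24 and essentially
linear at about 1 cm per week, uses a linear basis on [168, 310] days.
The random structure is an intercept per woman by default (a random
slope is available behind a flag); this is the smallest model adequate
for estimating a population *mean* curve and avoids the convergence
fragility of richer structures. Only what the mean curve needs is
consumed downstream, which is why a method-of-moments engine
(`engine = "moment"`) is offered as a fast alternative that agrees with
REML on $f_m$ at large $n$.

**Step 2 — u-scores.** A woman's departure from the population is the
residual $r_{ij} = y_{ij} - \hat f_m(t_{ij})$. At a landmark $w$ only
residuals with $t_{ij} < 7(w+1)$ days — strictly before the end of the
completed week — are used. Each woman's residual curve is summarised by
a least-squares fit on an orthogonal quadratic polynomial in centered
gestational age (centered at her own mean observed age, in weeks, and
orthogonalized on her own observation times), giving three
near-uncorrelated coefficients: **level** (mean departure), **trend**
(per week) and **curvature** (per week²). Each is standardized against
the distribution of the same coefficient among non-preeclamptic women
still at risk at that landmark, giving z-score-like *u-scores*. Scales
are estimated per landmark, because coefficient dispersion grows with
follow-up length, and a woman contributes to a scale only with enough
observations (1 for level, 2 for trend, 3 for curvature).

Degenerate visit histories are shrunk to the population mean rather
than dropped: with two observations the curvature is 0 and level/trend
come from the exact line, with one observation the level is the
residual itself, with none all three are 0 — so every at-risk woman
receives a feature vector and no imputation is ever performed. The
choice to *center* as well as scale (rather than divide by the
dispersion only) follows the z-score analogy; it is a genuine
alternative and is isolated in `fit_uscore_scale()` should anyone wish
to flip it.

**Step 3 — landmark risk models.** For each outcome and landmark a
logistic regression is fitted by maximum likelihood among the at-risk
women, on: the encoded baseline covariates (dummies against the largest
printed category as reference; explicit `missing` dummies), the 15
u-scores, the ever-high glucose flag (≥ 9 mmol/L at any visit in the
window) and two dipstick dummies (maximum category 1+ / ≥ 2+ in the
window). Five outcome labels are supported, with 259 days = 37 completed
weeks as the boundary: preeclampsia at any time; *preterm* preeclampsia
(delivery < 37 weeks); *term* preeclampsia (delivery ≥ 37 weeks); and
diagnosis before / from 37 weeks irrespective of delivery. Rare binary
covariates can separate at moderate sample sizes, so a detected
separation or non-convergence triggers a refit with a weak L2 penalty
(1e-4 on standardized columns, intercept unpenalized) and is flagged in
the model diagnostics. Performance is summarised per cell by the
Mann-Whitney AUC with a DeLong 95% CI and by the detection rate at a
10% false-positive rate with a stratified percentile-bootstrap CI
(2000 seeded resamples).

This two-stage pipeline (population curve → u-scores → GLM) is a
deliberate approximation of a shared-effects joint longitudinal model:
it keeps every stage auditable and cheap to refit, at the cost of
ignoring the uncertainty of the first two stages inside the third. For
discrimination-focused evaluation this primarily affects confidence
intervals, not the ranking of women.

### Risk sets and information flow

"Not yet affected" is operationalized as diagnosis before the end of
the completed landmark week; women already *delivered* by the landmark
are removed as well, since they are no longer predictable antenatally —
the second clause is forced by landmarking logic even though only the
first is usually stated. One consequence is mechanical: at week 36 the
preterm-preeclampsia outcome (delivery before day 259) has no cases
left in the risk set, and that cell is reported as absent rather than
fitted. The same risk-set rule serves all five outcomes. The no-leakage
property — perturbing any measurement taken at or after the end of the
landmark week leaves every landmark feature and prediction unchanged —
is enforced by construction and property-tested.

## The synthetic cohort generator

The registry data behind this design cannot be shared, so the package
ships a seeded generator (`generator_config()`, `simulate_cohort()`)
whose defaults are calibrated to the published cohort descriptives and
which serves as the test bed for the whole pipeline:

* **Size and outcome.** 58,899 nulliparous women at full scale; the
  outcome is drawn from a logistic model on the encoded baseline
  covariates whose coefficients reflect the published case/control
  contrasts, with the intercept solved numerically so the marginal
  incidence hits its 4.4% target regardless of the coefficient choice.
  Aspirin use is an independent 1.1% Bernoulli with no outcome effect —
  it exists to exercise the sensitivity-analysis filter.
* **Gestational ages.** Diagnosis age for affected women comes from a
  two-component (preterm/term) normal mixture with the preterm share a
  free parameter (default 0.25; the source material does not print this
  split); delivery follows diagnosis by a gamma-distributed delay, so
  diagnosis- and delivery-based outcomes are independently generable.
* **Visit schedules.** First visit near week 10 (clipped to days
  49–112), then trimester-dependent gaps that shorten toward term, and
  a further densification from 35 days before diagnosis in affected
  women. The gap means were calibrated once so the median visit count
  is 11 in unaffected and 12 in affected women, matching the published
  medians, and then frozen.
* **Markers.** Value = population polynomial mean (cubic in weeks,
  marker-specific center) + per-woman random intercept and slope +
  noise, rounded to clinical precision (1 mmHg, 0.1 kg, 1 g/L, 0.5 cm,
  0.1 mmol/L; blood pressure optionally to the nearest 5, mimicking
  recording practice). The blood-pressure and hemoglobin curves dip in
  the second trimester. Affected women's markers additionally follow a
  smooth departure ramp starting 35 days before diagnosis,
  $\ell\,(1-(1-\min(h,1))^2) + \tau h + \kappa h^2$ with
  $h = \max(0, t - t_0)/\text{lead}$, whose level/trend/curvature
  magnitudes are separately configurable; the defaults put most of the
  signal in curvature, the feature reported as most elevated in cases.
  Pulse pressure is floored at 2 mmHg (5 under nearest-5 rounding) so
  systolic always exceeds diastolic.
* **Categoricals.** Ever-high glucose probability 3.3% / 5.3%
  (controls / cases); dipstick maximum category 1+ with 10.5% / 26.0%
  and ≥ 2+ with 1.4% / 44.4%. Case elevations are placed at or after
  the departure onset, mimicking gestational proteinuria preceding the
  diagnosis.

What the generator does **not** emulate: physiological correlation
between markers beyond the shared outcome, measurement-occasion
correlation between e.g. weight and blood pressure, gestational
dating error, care-seeking feedback (extra visits *because* of high
readings, except for the diagnosis-driven densification), or any causal
effect of aspirin. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline recovers structure it is pointed at — not
that the published discrimination transfers to any particular clinic.
For the same reason the published AUCs themselves are not used as
numeric targets anywhere in the test suite; what is asserted is the
qualitative gradient (discrimination for preterm preeclampsia sharpens
from week 24 to week 32, and grows with the configured departure
magnitude).

## Numerical choices worth knowing

* Gestational age is stored in days; "completed week $w$" spans days
  $7w$ to $7w+6$, and every landmark window is $t < 7(w+1)$.
* The u-score basis is orthogonalized per woman with closed-form
  sufficient statistics; a brute-force normal-equations fit on the
  explicit basis agrees to 1e-10 and is kept as the test oracle.
  Duplicate observation times degrade gracefully (trend/curvature 0).
* Scale dispersions carry a 1e-8 degeneracy floor (error, not silent
  continuation); features with fewer than 30 contributing women are
  disabled and their columns flagged inactive rather than fitted —
  at week 24 this is the expected state of symphysis-fundal trend and
  curvature, which cannot have three observations between day 168 and
  the window end.
* The empirical ROC groups tied scores into single steps; the AUC is
  the midrank Mann-Whitney statistic; sensitivity at fixed FPR takes
  the most liberal threshold whose empirical FPR does not exceed the
  target, without interpolation — reproducible from finite samples and
  conservative.
* Evaluation is apparent (in-sample) by default, matching the design
  being reproduced, which reports no internal validation split;
  `holdout = TRUE` gives a seeded 50/50 split for honest synthetic
  benchmarking. In-sample evaluation with ~56 free parameters
  visibly inflates AUC when the true signal is null — the null-signal
  test accounts for exactly that.
* All randomness flows from one integer seed through a documented
  integer-arithmetic fan-out (`derive_seed()`), so changing the
  landmark list of a pipeline run never perturbs cohort generation, and
  artifacts of `run_pipeline()` are bit-reproducible (the wall-clock
  log aside).
* Zero-residual-variance training data (possible in synthetic
  exactness tests) makes REML degenerate; the trajectory fitter detects
  it and falls back to ordinary least squares, which is exact there.

## Problem sizes used in the shipped checks

The package's own test suite fits the full pipeline on cohorts of
2,000–20,000 women (five seeds at 20,000 for the gradient properties),
uses a single 58,899-woman simulation for the calibration checks, 1,000
replicates for DeLong coverage and the Mann-Whitney oracle, and 200–300
replicates for oracle equivalences — sizes chosen so every claim is
testable on a laptop while the Monte-Carlo error stays far below the
asserted margins.

## Known limitations

The approximation of the joint model is two-stage; scale estimates and
trajectory curves are treated as known in step 3. Coefficients of the
risk models are predictive, not causal. The generator's marker
departures are a stylized mechanism — a smooth ramp tied to the
diagnosis date — and real pre-diagnostic physiology is surely messier.
Calibration of predicted probabilities is out of scope (as is any
net-benefit analysis); only discrimination is evaluated.
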