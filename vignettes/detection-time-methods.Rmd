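---
title: "Models and methods: isoflupredone pharmacokinetics and detection time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: isoflupredone pharmacokinetics and detection time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoflupk)
```

## The problem

Isoflupredone acetate is a synthetic glucocorticoid given intramuscularly to
performance horses. Regulators screen plasma at 100 pg/mL (0.1 ng/mL): a
horse testing at or above that limit fails. The central quantity this
package computes is the *detection time* — the post-dose time by which a
stated fraction of a simulated population has fallen below the screening
limit — and the whole-day *withdrawal recommendation* derived from it.

## Structural model

A one-compartment model with first-order absorption and first-order
elimination, dosed extravascularly:

$$C(t) = \frac{D/BW}{V/F}\,\frac{k_a}{k_a-k_e}\left(e^{-k_e t}-e^{-k_a t}\right),
\qquad k_e = \frac{CL/F}{V/F}.$$

Units are pinned throughout: time in hours, concentration in ng/mL, dose in
mg, body weight in kg, V/F in L/kg, CL/F in mL/min/kg at the interface and
L/h/kg internally (factor 0.06). Mixed unit systems are the dominant failure
mode in this kind of analysis, so the conversion lives in one exported
function (`convert_clearance()`) and every constructor validates positivity.

Because dosing is extravascular, clearance and volume are apparent
(`/F`) quantities. Flip-flop kinetics (absorption slower than elimination,
`ka < ke`) is admitted — the closed form is symmetric in the two rates — and
when `ka` and `ke` coincide within 1e-6 relative, the degenerate limit
$C(t) = \frac{D/BW}{V/F} k_a t\, e^{-k_a t}$ is used; the two branches agree
to 1e-6 relative at the switch, which the tests verify.

The packaged population values are: tvKa 8.34 /h, tvV/F 27.9 L/kg, tvCl/F
10.1 mL/min/kg, giving `ke` = 0.0217 /h, an elimination half-life of 31.9 h,
and a model AUC to infinity of 59.3 ng·h/mL for 20 mg into a 556.5 kg horse.
`ke` is treated as derived from CL/V rather than as a primary parameter; the
two choices agree within rounding for these values.

## Population model and Monte Carlo detection time

Between-subject variability is log-normal and diagonal:
$\theta_i = \theta_{tv} e^{\eta_i}$, $\eta_i \sim N(0, \omega^2)$
independently for `ka`, `v_f`, `cl_f`. Two design choices matter here.

* **The variability values (0.5969, 0.1233, 0.0492) are interpreted as
  log-scale variances (ω²), not SDs.** This is the reporting convention of
  the population-PK software family these estimates come from, and it is
  the interpretation under which the simulated 99th-percentile crossing
  lands near the reference value of ~226 h; reading them as SDs roughly
  halves the tail crossing time (~150 h), far outside any plausible band.
* **No correlations are modelled** — none are reported. This is a known
  limitation, discussed below.

`detection_time_mc()` simulates `n = 1000` individuals (the configured
default) on the 0–408 h grid in 3 h steps, computes at each grid time the
empirical 50th and 99th percentiles across individuals, and interpolates
each curve's crossing of the screening limit.

Numerical definitions, fixed and documented:

* *Quantiles* use the linear-interpolation definition (R's default type 7).
* *Crossing times* locate the last grid time at or above the limit and
  interpolate **log-linearly** within the following interval. Concentration
  curves decay exponentially in the terminal phase, so log-linear
  interpolation is exact for mono-exponential decay; against a zero
  endpoint the code falls back to linear interpolation.
* The *last* down-crossing is used, so pre-peak times where the curve is
  still below the limit cannot truncate the answer.
* *Withdrawal days* are the 99th-percentile crossing time divided by 24 and
  rounded **up**: a regulatory recommendation must not under-cover.
* Residual (assay) error is **off** by default in detection simulations:
  the regulated quantity is the horse's plasma concentration, not a noisy
  measurement of it. A documented toggle turns it on
  (multiplicative, SD 0.187, truncated below at −1).

Under these defaults the median crossing is ~117 h and the 99th-percentile
crossing averages ~232 h across seeds (the tests report its seed-to-seed
SD, about 10 h at n = 1000), giving a 10-day recommendation. Note the
reference values this scenario targets are 118 h and 226 h: the median
matches closely, while the simulated tail sits ~3% high *systematically*
(its large-n limit is ~232.5 h). The likeliest cause is an unreported
positive correlation between the volume and clearance random effects in the
original fit, which would shrink the variance of `ln ke` and pull the tail
crossing in; with only the diagonal ω² available, the independent-eta
simulation is the defensible choice, and the whole-day recommendation is
unaffected. One consequence is worth stating plainly: with the tail centred
near 232 h rather than 226 h, individual seeds produce an 11-day ceiling in
roughly one seed in seven, so the "10 days at 18 of 20 seeds" stability
check in the acceptance suite sits at the boundary and can fail honestly.

The phrase "a sample of 12 horses simulated 1000 times" is ambiguous; this
package reads it as 1000 de novo individuals drawn from the population
distribution. The alternative reading (1000 replicates × 12 horses =
12 000 individuals) is available by setting `n = 12000`. Body weight is
fixed at the cohort mean 556.5 kg by default; per-horse sampling from
N(556.5, 58.4²) is behind the `sample_bw` flag, off by default, because
weight enters only through dose/BW and its variability is not part of the
reported model.

## Non-compartmental analysis

`run_nca()` implements the standard rich-profile NCA:

* **Peak:** observed maximum; ties broken toward the earliest time.
* **Terminal slope:** ordinary least squares of log concentration against
  time over every suffix of the quantifiable post-peak points with ≥ 3
  points; the window with the highest adjusted R² wins, ties within 1e-4
  resolved toward more points; the slope must be negative (a slope above
  −1e-12 /h is reported as terminal-phase-not-estimable). The peak itself
  is excluded from candidate windows *unless* it is the first quantifiable
  sample — a profile already in decline has no absorption phase to protect.
* **AUC:** linear trapezoid on rising or zero-bounded intervals,
  logarithmic trapezoid on falling intervals with positive endpoints
  ("linear-up/log-down"), from a (0, 0) anchor (a missing or below-LOQ
  time-zero record anchors zero — no drug is in plasma at an extravascular
  dose time).
* **Extrapolation:** `auc_inf = auc_last + clast/lambda_z`, with `clast`
  the last *observed* quantifiable concentration by default; a documented
  toggle substitutes the regression-predicted value.
* **Censoring:** embedded and trailing below-LOQ records are excluded from
  both regression and integration; they are never replaced by zeros or
  LOQ/2.

On dense noise-free model-generated profiles the NCA recovers `ke`, the
half-life and AUC to infinity within 1% of the closed forms — the oracle
equivalence the test suite enforces. On the actual sampling schedule the
terminal window is finite and `lambda_z` carries a small upward bias
(within 2% of `ke` noise-free), which is the familiar behaviour of
best-fit window selection.

## Two-stage population estimation

The package deliberately does not re-implement an FOCE-class mixed-effects
estimator. With 27 samples per horse the data are rich, and a two-stage
estimator reaches the same reportables:

1. **Stage 1.** Per horse, minimise
   $\sum_j (\ln C_{obs,j} - \ln C_{pred,j})^2$ over `(ka, cl_f, v_f)` — the
   least-squares criterion matched to multiplicative error — on the log
   scale (positivity by construction), with BFGS restarts until the
   relative parameter change is below 1e-8 and three jittered fallback
   starts on non-convergence. Initial values come from the data:
   `ke0` from the terminal slope, `v0 = (dose/BW)/Cmax` (bounded to
   [1, 500] L/kg), `ka0 = max(5 ke0, 5/tmax)` capped at 50 /h, `cl0 =
   ke0 v0`.
2. **Stage 2.** Typical values are geometric means of the individual
   estimates; ω² are the (n−1) sample variances of the logs; the residual
   SD is the pooled root-mean-square log residual; CV% of a typical value
   is $100\,\mathrm{sd}(\ln p)/\sqrt{n}$.

Model comparison sums per-subject AIC, `n ln(SSR/n) + 2k`, across subjects;
exact ties are flagged, not broken. Only the multiplicative residual
structure is parameterised — it is the structure the reportable estimates
assume — so candidate comparison in practice means structural candidates
(e.g. one-compartment vs mono-exponential).

Two-stage estimation is known to overstate between-subject variance when
individual estimates are noisy, and `ka` is the weakly identified parameter
on this schedule (few points on the absorption upswing). The parameter
recovery study in the acceptance tests — 20 replicate 12-horse cohorts with
the full residual noise — bounds the median absolute error of typical
clearance below 10% and of volume below 15%, and the round trip
simulate → fit → simulate reproduces the 99th-percentile detection time
within 15% in the median. Individual 12-horse cohorts can miss by more
(upward ω² noise maps into the tail), which is why the closure tolerance is
a median across replicates.

## Biomarker and electrolyte statistics

Fractional excretion is the creatinine-normalised ratio
$FE = \frac{U_x/P_x}{U_{cr}/P_{cr}} \times 100$; it is dimensionless in
each ratio, so any common rescaling of the analyte pair or the creatinine
pair cancels — a property the tests assert exactly.

Baseline-versus-time comparisons use the classical balanced one-within-factor
repeated-measures decomposition (subject, time, residual sums of squares;
`F = MS_time/MS_residual` on `(t−1, (n−1)(t−1))` degrees of freedom). For
balanced data this is exactly the random-intercept mixed model, and no
covariance structure beyond compound symmetry is estimable from a design
like this one, so the classical form is used directly; the test suite
cross-checks it against `aov()` with an error stratum. Post hoc comparisons
are paired t-tests of each post-baseline time against baseline, with
p-values multiplied by the number of comparisons (Bonferroni — named, not
Dunnett, which would be the sharper choice but not the documented one) and
capped at 1. Degenerate inputs are guarded: all-constant data report
`F = 0`, `p = 1`; a zero-variance, zero-mean difference reports `t = 0`,
`p = 1`. Subjects missing baseline are dropped with a warning; otherwise
unbalanced data get the ANOVA on complete-series subjects and
pairwise-complete post hoc tests with per-comparison n reported. The
pre/post electrolyte analysis is the same machinery with two time points,
which reduces to a Bonferroni-adjusted paired t-test.

## The synthetic-data generator

The generators exist so that every stage of the pipeline — file I/O, NCA,
estimation, detection, statistics — runs and is testable with no external
data. They emulate the *statistical structure* the analysis assumes, not
the biology:

* **Plasma** is the genuine forward model: population sampling,
  one-compartment kernel, multiplicative residual error (SD 0.187), LOQ
  censoring at 0.01 ng/mL with explicit BLQ flags (censored values are
  never written as zeros).
* **Urine** is a shape template: per-horse mono-exponential decline from
  24 h, `ln U24 ~ N(ln 13, 0.5²)`, decline rate `~ N(0.012, 0.002²)` /h,
  log-normal noise (sdlog 0.2), censored at 0.05 ng/mL. The decline rate
  default was chosen so that above-LOQ counts fall to ~0 by 360 h, matching
  the qualitative censoring pattern of the study design it emulates.
* **Cortisol** is a suppression template around a baseline drawn from
  N(52.0, 10.3²) ng/mL: fast onset (within the first hour) to a plateau at
  87% of the maximum, a Gaussian deepening (width 20 h) to the full
  maximum 0.9 at the 36 h nadir, then slow recovery (8e-4 /h), with 10%
  proportional noise. The template keeps suppression above 60% from 30 min
  through 312 h — a large, uniform effect size, deliberately so: its job is
  to make the power property ("every post-baseline time flagged") hold, and
  `suppression_max = 0` gives the exchangeable null used to calibrate the
  family-wise error. Eicosanoid-like series can be emulated by reusing the
  template with different signs and timings; no numeric targets are
  attached to them.
* **Electrolytes** draw plasma values from Normal distributions matching
  the cohort summary table (potassium 3.8 ± 0.71 pre to 2.7 ± 0.67 mmol/L
  post, and so on; for analytes summarised as median and range the SD is
  taken as range/4), and a target FE from a log-normal centred on the
  reported medians (potassium 39% pre, 69% post; log-SD `log(hi/lo)/4`);
  the urine analyte value is back-calculated so the emitted record's FE
  equals the drawn target. One documented inconsistency in the source
  summaries — the pre/post potassium SDs appear swapped between the text
  and the table (0.67 vs 0.71) — is resolved in favour of the table and
  otherwise left alone. `effect = FALSE` makes post exchangeable with pre.

What passing tests on these data do **not** show: correct behaviour under
real assay drift, inter-occasion variability, correlated random effects,
non-log-normal tails, or cortisol circadian structure — none of which the
generators emulate.

All generators are deterministic under a seed (`gen_study()` derives
per-file offsets from the configured seed) and no emitted quantifiable
value sits below its LOQ.

## Problem sizes and numerical conventions

The test and acceptance suites use: 20 replicate Monte Carlo runs of 1000
individuals for the detection-time checks; 20 replicate 12-horse cohorts
for parameter recovery; 1000 simulated null cohorts for the family-wise
error calibration; dense grids (0.05–1 h steps out to 1200–5000 h) for the
oracle-equivalence and AUC-conservation checks. These sizes were chosen so
that Monte Carlo error is small relative to each asserted tolerance while
the whole suite stays quick on a single CPU.

Other conventions: optimizer convergence at 1e-8 relative parameter change;
adjusted-R² ties at 1e-4 resolved toward longer windows; quantile type 7;
log-linear crossing interpolation with a linear fallback against zero; RNG
draws in `sample_individuals()` are parameter-major (all `ka`, then `v_f`,
then `cl_f`), which fixes the exact reproducible stream for a given seed.

## Limitations

* Diagonal ω² only; any true V–Cl correlation is unmodelled, and the
  simulated 99th-percentile detection time inherits a small (~3%) upward
  offset relative to the reference scenario, as discussed above.
* The two-stage estimator is not an FOCE replacement for sparse designs;
  it relies on the rich 27-point schedule.
* No confidence machinery is attached to the point detection times: a
  stated "95% confidence level" in the emulated scenario is not connected
  to any reported interval, so none is invented here; seed-to-seed spread
  is reported instead.
* Urine is summarised (censored means, counts), never PK-modelled; no
  urine detection times are produced.
* Cortisol and eicosanoid templates are effect-size dials for the
  statistics stage, not pharmacodynamic models.
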