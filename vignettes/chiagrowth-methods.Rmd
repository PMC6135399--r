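---
title: "Methods: thermal-time growth analysis for chia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal-time growth analysis for chia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiagrowth)
```

`chiagrowth` implements the full analysis chain used to characterize the
growth of chia (*Salvia hispanica* L.) in field trials: thermal time,
reference evapotranspiration and deficit-irrigation dosing,
double-logistic trajectory fitting, functional growth analysis, and the
treatment statistics. This vignette is the package's own account of the
underlying models, the tunable parameters, and the design decisions taken
where the methodology left genuine choices open.

## Thermal time

Development is driven by temperature, so all trajectories are expressed
against accumulated growing degree days (ADD) rather than calendar days.
The daily increment is the De Candolle form

$$\mathrm{GDD}_i = \max(0,\; T_i - T_b),$$

with the daily mean temperature $T_i$ defaulting to
$(T_{min}+T_{max})/2$ — the conventional choice when only extreme
temperatures are recorded — and the base temperature $T_b = 10\,°C$
appropriate for chia's subtropical origin. Clamping is applied *per day*
before summation, so cold days never erode accumulated heat and the
cumulative series is non-decreasing by construction. Day 0 is the sowing
day; accumulation therefore starts at sowing. Phenology tables for other
baselines (e.g. accumulation from emergence) can be derived by
differencing stage values, which is why the baseline is not a hidden
switch. Chia stops developing above roughly 36 °C, but the accumulation
formula deliberately carries no upper cutoff by default (an optional
`tceiling` exists): the trial climates rarely exceed that ceiling and the
uncapped form matches how the reference coefficient sets were estimated.

Harvest days rarely coincide with the daily weather grid, so
`das_to_add()` interpolates the cumulative series linearly. Linear
interpolation is exact for the daily-resolution model (ADD is piecewise
linear in time between daily increments).

## Reference evapotranspiration and irrigation dosing

No crop coefficient is established for chia, so irrigation is scheduled
directly on reference evapotranspiration. `eto_penman_monteith()` is the
FAO-56 Penman–Monteith equation, exactly as standardized: auxiliary
terms use the Tetens saturation curve
$e_s(T) = 0.6108\,e^{17.27T/(T+237.3)}$, its slope
$\Delta = 4098\,e_s/(T+237.3)^2$, and $\gamma = 0.000665\,P$. Two
numerical notes:

* FAO-56 rounds $17.27 \times 237.3 = 4098.17$ to 4098 in $\Delta$; the
  formula is therefore ~$4\times10^{-5}$ relative away from the true
  analytic derivative of $e_s$. The tests account for this.
* Computed ETo can be negative (radiative loss exceeding soil heat flux
  under saturated air). The value is returned as computed — truthful to
  the equation — and the *scheduler* treats negative days as contributing
  zero to the accumulator (`clamp_negative = TRUE` there by default).

Missing inputs are derived the FAO-56 way: $e_a = (RH/100)\,e_s$ when
only mean humidity is available, $e_s$ as the mean of the saturation
pressures at the daily extremes, pressure from site elevation by the
barometric formula. Defaults: sea-level pressure 101.3 kPa, soil heat
flux 0 at daily resolution.

The irrigation criterion accumulates daily ETo and fires an event
whenever the running sum reaches the trigger, applying
`fraction × accumulation` litres per square metre and resetting the
accumulator. The trigger default is 8 mm — the worked value inside the
protocol's 5–10 mm band — and the trial fractions are 1.0 (full
replacement) and 0.4 (deficit). A trailing sub-trigger accumulation at
season end emits no event, matching a criterion that only ever irrigates
on threshold crossings. Total applied depth is then exactly linear in
the fraction, which the tests exploit.

Weekly summaries of ETo are a reporting view; the scheduler always
operates on daily values.

## The double-logistic growth model

Biomass and leaf area over thermal time $t$ follow

$$y(t) = y_{min} + (y_{max}-y_{min})\left[\frac{1}{1+e^{-m_S(t-S)}} +
\frac{1}{1+e^{\,m_A(t-A)}}\right],$$

a growth logistic with inflection $S$ and rate $m_S$ summed with a
senescence logistic with inflection $A$ and rate $m_A$. The
implementation evaluates the logistic terms through `plogis()`, which is
exact and overflow-safe for exponents of any magnitude.

### Interpreting the asymptote parameters

This functional form (without the $-1$ term some double-logistic
variants carry) has the property that the *sum of the two bracket terms
is ≈ 1 at both ends of the season* whenever $S < A$ and the rates are
positive: the early-season baseline is $y_{min} + (y_{max}-y_{min})$,
not $y_{min}$. Consequently fitted $y_{min}$ and $y_{max}$ are empirical
asymptote parameters, not observable masses — the reference coefficient
sets shipped in `chia_reference_coefficients()` carry strongly negative
$y_{min}$, $y_{max} \approx -y_{min}$, and negative $m_S$. No sign or
ordering constraints are imposed during fitting for exactly this reason
(optional box bounds exist but default off).

Evaluated through the printed model, those published sets trace smooth
*monotone-declining* curves on 0–1400 ADD (e.g. the SD1 biomass set runs
from ≈199 g at $t=0$ down to ≈11 g) rather than the rise-and-fall
trajectories the trials describe (peak dry mass ≈30 g plant⁻¹, peak leaf
area ≈1187 cm² plant⁻¹). The package treats them as what they
operationally are: internally consistent parameter vectors that
round-trip through the fitter. For work that needs *realistic*
trajectories — exercising the growth-index layer, demonstrating
treatment contrasts — `chia_calibrated_truth()` provides synthetic
coefficient sets calibrated against the reported summary landmarks (peak
biomass ~30 g at ~1100–1150 ADD; peak RGR ~0.15 and ~0.11 g g⁻¹ d⁻¹
near 410 ADD for the two sowing dates; leaf-area peaks of ~1160 and
~1187 cm²; the smaller, earlier irrigation-trial trajectories). These
are labelled *calibrated* everywhere: they are constructed, not fitted
to raw data.

### Identifiability

The model is exactly invariant under exchanging the two terms,
$(m_S, S) \leftrightarrow (-m_A, A)$: both labellings describe the same
curve. Fits are therefore canonicalized to $S \le A$
(`dl_canonical()`), so the growth inflection is always reported in the
same slot and coefficient tables are comparable across treatments. A
second, practical limit: a very steep transition (width $\approx 4/m$)
narrower than the sampling interval leaves its rate parameter
under-determined — the zero-noise recovery tests sample the steepest
reference set at 2-ADD steps for this reason.

### Fitting

`fit_double_logistic()` minimizes the residual sum of squares with
damped (Levenberg–Marquardt) least squares via `minpack.lm::nls.lm`.
Convergence uses a relative SSE-reduction tolerance of $10^{-10}$ and a
step-norm tolerance of $10^{-12}$; results carry convergence flags,
iteration counts and a covariance estimate from the damped Hessian
(flagged when rank-deficient). Because the SSE surface of a 6-parameter
double logistic has local minima, the solver is started from:

1. a heuristic guess — asymptotes 10% beyond the data range, inflections
   at the first upward / last downward half-range crossings, rates
   $4/\text{(crossing width)}$, with a monotone-decline fallback and a
   flagged default $A = \max(t)$ when the series never declines;
2. the term-swapped twin of that guess; and
3. five seeded random restarts (log-normal perturbation of rates,
   Gaussian perturbation of inflections and asymptotes).

The lowest SSE wins; ties break to the first found. Fitting is on the
ADD axis by default (pass a DAS axis to fit on calendar time).

### Goodness of fit

Per-treatment fit quality is reported as four columns: `rmse`
$=\sqrt{SSE/n}$, `error` $=\sqrt{SSE/(n-6)}$ (the residual standard
error), $R^2 = 1 - SSE/SST$, and the regression F-test p-value on
$(5, n-6)$ degrees of freedom. The two residual scales satisfy
$n\,\mathrm{rmse}^2 = (n-6)\,\mathrm{error}^2$ identically; the pair is
reported because published coefficient tables for this crop print both,
and their ratio pattern identifies the denominators. The coefficient-set
comparison `compare_fits()` pairs the six coefficients of two fits and
runs a two-sided paired t-test — the most direct reading of how such
fits have been compared; a whole-curve F-test on pooled residuals would
be the main alternative, and the choice matters little for the extreme
p-values that occur in practice. Degenerate inputs are handled by
convention: identical coefficient vectors give $p = 1$, an exactly
constant shift (zero variance of differences) gives $p = 0$ with a
warning.

## Growth indices

Classical (interval) indices follow Hunt's formulas on treatment-mean
trajectories — means of the sampled plants per harvest, matching how
such trials are plotted; a per-plant route is available by filtering the
observation table. Rates are per *calendar day* (the conventional
units), while the reporting axis is thermal time: interval midpoints
carry both `das` and `add` (via `das_to_add()`).

$$\mathrm{RGR} = \frac{\ln w_2 - \ln w_1}{t_2-t_1}, \quad
\mathrm{NAR} = \frac{w_2-w_1}{t_2-t_1}\cdot
\frac{\ln a_2 - \ln a_1}{a_2-a_1}, \quad
\mathrm{CGR} = d\,\frac{w_2-w_1}{t_2-t_1},$$

with the NAR limit $(w_2-w_1)/((t_2-t_1)a_1)$ used when
$|a_2-a_1| < 10^{-9}$. Negative interval rates during senescence are
preserved. Two naming notes inherited from the field: the ratio reported
for chia under the name LWR (cm² kg⁻¹) is leaf *area* per total dry
mass — conventionally LAR; both names are exposed
(`lwr = 1000 × lar`). And the reported maximum LAI of 8.5 for the
sowing-date trial is inconsistent with its own peak leaf area × density
($1187 \times 50 / 10^4 = 5.9$); the package computes
`lai = leaf_area × density / 1e4` and leaves the discrepancy recorded
here rather than resolved.

Functional indices evaluate the fitted curves: $\mathrm{RGR} = W'/W$,
$\mathrm{NAR} = W'/A$, $\mathrm{LAR} = A/W$, $\mathrm{CGR} = d\,W'$,
$\mathrm{SLW} = f_{leaf}\,W/A$ for a supplied leaf-mass fraction. The
identity $\mathrm{RGR} = \mathrm{NAR}\times\mathrm{LAR}$ then holds
*exactly* on the evaluation grid, and interval RGR equals the
time-average of instantaneous RGR for any positive smooth $W$ — both are
enforced as tests. Rates come out per degree-day unless a thermal series
is supplied, in which case the local ADD-per-day slope converts them to
per-day (this conversion cancels in the RGR = NAR × LAR identity).

Plant densities default to the trial protocols: 50 plants m⁻² for the
sowing-date trial, 60 (midpoint of the 55–65 thinning band) for the
irrigation trial.

## Statistics

The irrigation trial was laid out as a split-plot, but treatment
significance at individual harvests is assessed — as it is reported in
practice — by per-time-point one-way comparisons: `one_way_anova()`
(computed through `stats::lm`/`anova`) followed by `duncan_mrt()`. This
simplification is deliberate and visible; no mixed-model machinery is
hidden underneath. No multiplicity correction is applied across time
points, matching the reporting convention.

Duncan's critical range for a span of $p$ ordered means is
$q\,\sqrt{MSE/n}$ with $q$ the studentized-range quantile at protection
level $(1-\alpha)^{p-1}$ — computed from `qtukey()` rather than
interpolated from printed tables, for reproducibility at arbitrary error
degrees of freedom. For $p = 2$ this reduces exactly to the LSD t-test
($q_{2} = \sqrt{2}\,t_{1-\alpha/2}$), which the tests verify. Letters
are assigned by the standard sweep over maximal non-significant
stretches of the descending means, so letter groups are contiguous and
order-consistent. Near-balanced groups use the harmonic mean group size.

`correlation_matrix()` reports Pearson r with p-values from
$t = r\sqrt{(n-2)/(1-r^2)}$; zero-variance series produce `NA` with a
warning, never a silent zero.

## The synthetic-data generator

The generator exists so that every stage is exercised end-to-end with
known truth. It emulates:

* **Weather** — a sinusoidal annual temperature cycle (southern
  hemisphere phase, peak mid-January) plus seeded Gaussian daily noise;
  humidity, wind and net radiation drawn around profile means. The
  Antumapu profile uses the stated 14 °C annual mean with a 6.5 °C
  seasonal amplitude and 14 °C diurnal range from Santiago climate
  normals; Intihuasi is derived from its stated January maximum (28 °C)
  and July minimum (5 °C) with a 13 °C diurnal range. Under these
  profiles a 7-December sowing accumulates ≈1090–1120 ADD by the
  121-DAS flowering date, consistent with the reported 1140 within the
  between-year variability such records show.
* **Plant harvests** — per treatment × block × harvest, `n_plants = 10`
  destructive observations: truth curve value at the harvest's thermal
  time plus Gaussian noise, with organ masses split by a smooth
  phenology-indexed allocation schedule (vegetative 45/40/15/0%
  leaf/stem/root/inflorescence, ramping to 18/40/12/30% over the 300 ADD
  after flowering) so that `dm_total` equals the organ sum exactly.
  Noise sds default to the published per-treatment fit residuals
  (0.243–1.2865 g for biomass, 35.8–137.0 cm² for leaf area), pooled
  across blocks and plants — the within/between-plot partition is not
  reported, so a single pooled sd is the defensible minimum. Negative
  draws are *redrawn* (truncation), not clamped, to avoid a point mass
  at the floor (0.01 g / 1 cm²).
* **The deficit effect** — `apply_deficit_effect()` scales both
  asymptote parameters by $(1 - \text{reduction})$, which scales the
  whole trajectory pointwise; the published 54% dry-matter and 43%
  leaf-area reductions then propagate exactly to the season maximum and
  the season integral. (Scaling the range while holding $y_{min}$ fixed
  — the other conceivable reading — translates the curve downward under
  this parameterization and can push it entirely negative, so it was
  rejected.)

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: no process physiology (no
radiation interception, water balance or stress dynamics — the deficit
effect is imposed on the truth curves, not emergent), homoscedastic
noise (real destructive-harvest variance grows with plant size), no
spatial or block structure beyond labels, no measurement error in leaf
*area* distinct from leaf *mass*, and no frost or pest damage. One
visible artifact is worth knowing: at the earliest harvests the truth
biomass (~0.03 g) is far below the noise sd (~0.5 g), so truncation at
the floor inflates early means and biases early interval RGR downward —
trajectory-level checks therefore evaluate the noise-free mean
trajectory.

## Numerical choices and problem sizes

* Fit tolerances: `ftol = 1e-10`, `ptol = 1e-12`, max 400 iterations,
  5 restarts; ties by first-found.
* The recovery study fits 57 observations (0–1400 ADD at 25-ADD
  cadence) per replicate, 20 seeded replicates, reporting medians —
  small enough to run in seconds, large enough that the median
  inflection recovers to a fraction of a percent.
* Property tests run 8–25 seeded repetitions per invariant; quadrature
  oracles use 2×10⁴-point trapezoid grids.
* All randomness flows through explicit seeds; the pipeline derives
  fixed per-stage substreams from one root seed, and its manifest
  records everything needed to reproduce a run.

## Known limitations

* The published coefficient sets and the described trajectories cannot
  both be honoured by one curve (see above); the package makes the
  tension explicit rather than silently preferring either.
* Fitting on ADD treats thermal time as error-free; uncertainty in the
  weather record does not propagate into coefficient covariances.
* The Duncan implementation assumes the one-way error structure it is
  given; it does not recover split-plot error terms.
* `initial_guess()` presumes a single rise and/or single decline;
  multimodal trajectories (regrowth after damage) are outside the model
  family by construction.
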