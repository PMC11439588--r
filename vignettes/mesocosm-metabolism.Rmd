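---
title: "Models and methods: mesocosm metabolism under simulated heatwaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: mesocosm metabolism under simulated heatwaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesometab)
```

mesometab turns high-frequency oxygen, temperature and irradiance sensor
series from closed mesocosm incubations into community-metabolism
estimates: hourly net community production (NCP) rates,
photosynthesis–irradiance (P–I) model fits, accumulated production with
Monte-Carlo uncertainty, and heatwave exceedance statistics. This
vignette explains the models, the choices behind every default, and what
the included synthetic-experiment generator does and does not emulate.

## The measurement model

A closed incubation turns a mesocosm into a bottle: with inflow shut,
the O₂ concentration drifts at the net community production rate. For
each hour-long window $[t, t+1\,\mathrm{h})$ of an incubation we regress
concentration on time by ordinary least squares; the slope (µmol L⁻¹
h⁻¹), its standard error and $r^2$ come straight from the regression.
The volumetric slope is converted to an areal rate normalised to the
tank footprint:

$$\mathrm{NCP}\;[\text{mmol O}_2\,\text{m}^{-2}\,\text{h}^{-1}]
  = \text{slope} \times \frac{V}{1000\,A},$$

with $V$ the volume in litres (default 1000) and $A$ the footprint in m²
(default a 1.1 m circle, ≈0.95 m²). Rates in mg L⁻¹ h⁻¹ are first
converted with the 31.998 g mol⁻¹ molar mass of O₂; units must be
declared, never guessed. An hourly window needs at least 3 retained
samples spanning at least 30 minutes. Hour windows are anchored at the
incubation start — the only anchoring that yields exactly three hourly
rates from a 3-h incubation. The mean retained temperature and
irradiance of the same hour are attached as the rate's context; all
retained 1-min samples are used (no decimation). Mild temperature drift
during incubations is accepted, not corrected.

## Quality control

Before any rates are computed, each sensor series is screened:

* temperature and salinity by an empirical percentile filter (defaults
  0.001 and 0.995): samples strictly outside those quantiles are masked;
* irradiance by a Tukey-style fence $[Q_1 - k\,\mathrm{IQR},\;
  Q_3 + k\,\mathrm{IQR}]$ with $k = 1.2$.

Quantiles use linear interpolation (type 7) and are computed from **all**
finite values of a series, not only currently-retained ones — this makes
every filter idempotent, which we treat as a contract (applying a filter
twice must change nothing). Filters only ever update the logical `qc`
mask; values are never altered and series never shortened, which keeps
replicate alignment trivial. Filters are applied per mesocosm (the
screening thresholds are order statistics of each sensor's own record;
pooling across tanks would let one warm treatment mask another's valid
data).

One pipeline-level refinement: the irradiance fence is applied within
mesocosm-days (`iqr_by_day = TRUE`). Irradiance is strongly diel and
nonstationary across a 3-week season; a fence over the pooled series
flags the real midday values of clear days — hours of them in a row —
rather than sensor errors. Within a day the diel distribution passes its
own fence untouched while genuine spikes are still caught. The
whole-series behaviour remains the function default and the documented
semantics of `filter_iqr()`.

## P–I curves and the temperature-modified model

The saturating P–I relationship is the hyperbolic tangent form

$$\mathrm{NCP}(I) = P_{max}\tanh\!\left(\frac{\alpha I}{P_{max}}\right) + CR,$$

with $P_{max}$ the asymptotic production (mmol O₂ m⁻² h⁻¹), $\alpha$ the
initial slope (photosynthetic efficiency), and $CR$ the community
respiration intercept (negative by sign convention). The compensation
irradiance — where the curve crosses zero — is
$I_c = (P_{max}/\alpha)\,\mathrm{atanh}(-CR/P_{max})$, with a
delta-method standard error from the coefficient covariance. Rates are
pooled across treatments into four non-contiguous temperature bins
(low 7.5–8.5, medium 10.1–11.1, high 11.5–12.6, extreme 13.0–13.5 °C;
intervals closed on the left, open on the right; rates outside every bin
are excluded) and one curve is fitted per bin. The extreme bin drops the
$CR$ term: its observations are light-saturated and warm, leaving the
intercept unconstrained.

The aggregate temperature-modified model incorporates a negative
temperature effect directly. Its published algebra is typeset
ambiguously, so both readings are implemented and switchable:

* **shifted** (primary): $\mathrm{NCP} = (P_{max}-T)\,
  \tanh\!\big((\alpha I - T)/P_{max}\big) + R_d$. Temperature lowers the
  asymptote *and* shifts the tanh argument, moving light saturation to
  higher irradiance as it warms — the behaviour reported for the fitted
  model, and the reason this reading is the default. The units inside
  the argument are heterogeneous as printed; we implement it literally
  and document that.
* **scaled** (alternative): $\mathrm{NCP} = (P_{max}-T)\,
  \tanh\!\big(\alpha I/(P_{max}-T)\big) + R_d$, a temperature-scaled
  classic curve. Its $R_d$ is an interpretable dark-respiration
  intercept, whereas the shifted reading absorbs much of respiration
  into the temperature shift and typically leaves $R_d$ small and
  non-significant — consistent with respiration being fit poorly by the
  aggregate model.

### Fitting

All curves are fitted by Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`). Binned fits are robust by default: iteratively
reweighted least squares with Tukey bisquare weights (tuning constant
4.685, scale = median absolute residual / 0.6745), converged when the
maximum relative coefficient change falls below 10⁻⁸ (at most 100
iterations). Coefficient standard errors come from the final weighted
fit; `rmse` is $\sqrt{SSE/(n-p)}$ on unweighted residuals.

Three numerical choices matter and are worth stating plainly:

1. **Starting values.** The primary start is deterministic and
   data-driven: $P_{max}$ from the highest observed rate, $\alpha$ from
   an OLS line through the five lowest-irradiance points, $CR$ from the
   lowest rate. That start is singular whenever the five lowest-I points
   are themselves light-saturated, so a deterministic ladder of
   fallback starts places the saturation onset at the irradiance
   quartiles; all candidates are fitted by plain least squares and the
   lowest-SSE solution wins.
2. **Robustness is anchored.** The bisquare IRLS starts from the best
   plain least-squares solution. Started anywhere else on a sparse
   design, the reweighting can discount an entire limb of the curve as
   "outliers" and converge to a degenerate straight-line basin.
3. **A physical box constraint.** Since $\max y \le P_{max} + CR$ and
   $\min y \ge CR$, the asymptote cannot exceed roughly the observed
   rate range; we constrain $P_{max} \le 1.5\,(\max y - \min y)$ (and
   $P_{max} \le 2 \max y$ for the intercept-free variant), with
   $\alpha > 0$ and $CR \le 0$. Without the ceiling, data carrying a
   respiration offset look *convex* through an origin-constrained tanh
   — whose best concave approximant is a line, i.e. $P_{max} \to
   \infty$ along a flat-SSE ridge. The bound excludes only that
   degenerate basin; recovery of true parameters requires the design to
   reach at least about half-saturation, which every shipped design
   does.

Predictions carry delta-method normal confidence intervals from the
coefficient covariance.

## Accumulated production and Monte-Carlo uncertainty

Hourly treatment drivers (replicate-mean, QC'd temperature and
irradiance) feed the fitted aggregate model to predict hourly NCP over
the full experiment. Accumulated production sums **positive** hourly
rates only — the model's respiration end is not trusted for
accumulation — giving rate × h units (mmol O₂ m⁻², also reported as
mol). Note the study's printed accumulated totals (736–915 "mol O₂
m⁻²" over three weeks) are about two orders of magnitude larger than
the integral of hourly rates in mmol can produce; we read this as a
units slip in the source and report both scales without forcing
agreement.

Uncertainty: 1000 Monte-Carlo iterations redraw every hourly rate from
its prediction uncertainty and repeat the positive-only accumulation;
the 2.5% and 97.5% quantiles of the totals are the interval. "Within
the 95% CI" is distributionally underspecified, so the default draw is
normal with sd = half-width/1.96 (the CI itself is delta-method normal);
uniform-on-the-interval is available. Draws are independent across hours
— no correlation structure is claimed. Driver gaps of at most 2 h are
linearly interpolated; longer gaps are an error, never silently filled.
Treatments are compared as percent decrease relative to the control,
rounded to the nearest integer for reporting, with a flag for 95% CI
overlap.

## Heatwave severity

For an hourly treatment temperature series and a threshold (default
11 °C — the temperature at which fitted production coefficients visibly
decline), `hours_above()` counts samples strictly above the threshold
(boundary values are not exceedances). Exceedance episodes are maximal
runs of consecutive exceedance hours; within each episode the running
sum of $T_i - \text{threshold}$ accumulates (°C h). The published
severity formula is irreconcilable as printed (the duration term's
placement conflicts with its reported unit), so both candidate readings
ship: the default reports the raw running sums; `per_hour = TRUE`
divides by elapsed episode duration, matching a mean-exceedance
reading. Histograms report relative frequencies (%) per bin and sum
to 100.

## The synthetic experiment generator

The generator reproduces the study design so every stage can be tested
against known ground truth: 12 mesocosms (4 treatments × 3 replicates),
23 days from 2022-06-30, 1-min O₂/temperature/salinity, 10-min
irradiance, weekly light incubations for control/HT, additional
peak-and-remission incubations for the heatwave treatments, and two
all-mesocosm dark incubations (days 1 and 10). One master seed drives
every stream through a documented splitting scheme; equal seeds give
byte-identical output files.

**Temperature.** Treatment offsets are continuous piecewise-linear: 48 h
acclimation, a 3-day ramp (~0.6 °C day⁻¹) to the +1.8 °C baseline, 48 h
hold, then the heatwave programme — 1MH ramps 1 °C day⁻¹ to a +2.8 °C
plateau held 13 days; 2MH ramps to +3.9 °C twice, 5-day plateaus
separated by 3 days at baseline. The 2MH ramps default to 2.8 °C day⁻¹:
at the generic 1 °C day⁻¹ the double-peak programme cannot fit inside a
23-day experiment (it would need ~21 days after the baseline hold where
only 16 exist); 2.8 °C day⁻¹ ends the programme exactly at day 23.
Ambient is a transparent construction (the study used real seawater):
linear seasonal trend + diel sinusoid + AR(1) noise, calibrated so the
23-day median falls in the 8.5–11.4 °C band reported for the source
sites, control and baseline stay mostly below ~11 °C, and the 2MH peaks
reach the extreme bin (≥13 °C). Per-mesocosm AR(1) deviations (0.08 °C)
emulate imperfect regulation.

**Irradiance.** Hourly values are numerically at the logger's
µmol m⁻² s⁻¹ scale; daily integrals use the logger convention
$\sum \text{hourly} \times 3600/10^6$ mol photons m⁻² d⁻¹ and land in
the reported 14–65 range exactly (each day is renormalised to its
target). The source's own irradiance numbers cannot all be honoured at
once — daily integrals of 14–65 mol imply hourly values ~25× larger
than the reported hourly maxima — and this convention is the one its
derived quantities check out under. Weather is synoptic: overcast
conditions at the range floor with one ~5-day clear spell (Gaussian,
centred day 16) reaching the ceiling, plus a brief weaker clear
interlude around day 2, day-to-day AR(1) noise, hourly lognormal cloud
modulation shared across tanks, per-mesocosm "rotating shadow"
modulation (under the midnight sun the solar azimuth sweeps the full
circle daily, so neighbouring structures shade each tank differently),
and per-treatment placement factors — the study itself reports that
random placement across the outdoor array caused systematic differences
in received flux. All modulations preserve daily integrals exactly.

**Ground truth.** O₂ traces are integrated from a known production
model plus Gaussian sensor noise (2.5 µmol L⁻¹ — optode precision; the
study's fit RMSE of 2.6–3.8 additionally contains biological scatter the
generator does not model). The default truth (`model_form =
"empirical"`) is a per-temperature tanh P–I curve whose coefficients
carry a built-in negative temperature effect: $P_{max}$ = 22 at 8 °C
declining logistically across an 11 °C threshold (width 0.35 °C) to a
45% floor, $\alpha$ = 0.06 decaying e-fold per 5 °C, $CR$ = −5
deepening slightly with warmth. Under this truth the binned fits are
exactly specified, and the aggregate temperature-modified model plays
its real-world role of an approximating fit — neither algebraic reading
of the aggregate model, used *as* the truth, can reproduce the observed
decline of both binned $P_{max}$ and $\alpha$ (the shifted reading
inflates warm-bin $P_{max}$ through its saturation shift; the scaled
reading fixes $\alpha$ across temperatures). The two aggregate forms
remain available as generating models for recovery studies.

**What the defaults deliberately encode.** The study's headline result —
the long moderate heatwave depressing accumulated production more than
two short intense ones — cannot arise from a static monotone
temperature response alone: the double-peak treatment accrues more
offset degree-hours (~21 vs ~14 °C d above the warming baseline), so
under a featureless sky it always loses more. The ordering emerges only
when the temperature response saturates above the threshold (extra
degrees beyond full suppression do no extra harm) *and* the weather
co-times with the events: overcast during the intense peaks, clear
during the inter-peak gap when only the long heatwave is elevated, with
the placement-driven light differences adding to it. The defaults
encode exactly that regime, which is a scientific statement in itself:
the relative severity of heatwave scenarios measured by accumulated
production depends on when the sun shines relative to the events, not
on the temperature programme alone. Conclusions drawn from the default
scenario reflect these conditions; both the weather and the response
shape are fully configurable for sensitivity analyses.

**What passing tests do and do not show.** The generator has no
biological state: no acclimation drift, no biomass change, no recovery
physiology, no hydrodynamics or heat budget, and replicate tanks differ
only through sensor-level and irradiance-level noise. Tests against it
validate the *pipeline* — filters, regressions, fits, propagation,
severity — under controlled truth; they cannot validate the biology of
any particular field system.

## Problem sizes and runtimes

The default experiment is 12 mesocosms × 23 days at 1-min cadence
(~1.2 M sensor samples), 90 incubation windows, 270 hourly rates, and
Monte-Carlo intervals at 1000 iterations; a full `run_analyze()` takes
well under a minute. Recovery studies in the test suite use 200
repetitions at the source design sizes (n = 34 per bin, n = 171 for the
aggregate model).

## Known limitations

* The extreme-temperature bin is intrinsically low-information (one or
  two incubation days, no respiration intercept); its coefficients are
  reported with honest, wide standard errors and should not be
  over-read.
* Delta-method intervals are first-order normal approximations; for
  strongly curved regions of parameter space a bootstrap would be more
  faithful.
* The empirical-quantile filters assume each mesocosm-series is mostly
  clean; they screen tails, not drift or bias.
* Monte-Carlo accumulation ignores temporal correlation of prediction
  errors, so its intervals are, if anything, slightly narrow.
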