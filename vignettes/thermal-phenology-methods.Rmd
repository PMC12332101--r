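---
title: "Thermal development models and voltinism projection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal development models and voltinism projection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotherm)
```

## The problem

Egg parasitoids such as *Telenomus remus* and *Trichogramma foersteri* are
released against lepidopteran pests; how fast they develop is governed
almost entirely by temperature. The standard workflow in insect thermal
ecology is to (1) rear the insect at a series of constant temperatures and
record mean development time, (2) fit a set of candidate rate functions to
the development *rate* (the reciprocal of time, d^-1), (3) select a
function using both fit statistics and the biological credibility of the
thermal parameters it implies, and (4) drive the selected curve with daily
temperature series to estimate *voltinism* — the number of generations per
year — under present and warmed climates. `phenotherm` implements that
whole chain.

## The model set

Twelve rate functions are supported (see `model_names()`): a linear
degree-day model and eleven nonlinear thermal performance curves
(Brière-1/2, Kontodimas, Lactin-1/2, Logan-6, Performance-2, Shi, Taylor,
a β-type power function and a four-parameter beta function). Each defines
a development rate $r(T) \ge 0$ over temperature $T$ (°C). Three derived
quantities carry the biology:

* $T_L$ — lower threshold, below which development stops;
* $T_{opt}$ — temperature of maximal rate;
* $T_H$ — upper threshold, above which development stops;
* for the linear model $r(T) = a + bT$, the thermal constant
  $K = 1/b$ (degree-days) and $T_L = -a/b$.

Depending on the functional form each threshold is an explicit parameter,
a derived quantity, or undefined:

* explicit: e.g. $T_L$, $T_H$ in the Brière, Kontodimas, Performance-2 and
  Shi models; $T_{opt}$ in the Taylor and beta functions.
* derived numerically: $T_{opt}$ for most models (dense 0.01 °C grid scan
  plus golden-section refinement, `derive_topt()`); zero crossings for
  e.g. the β-type upper limit and the Lactin-2 lower limit (sign scan plus
  bracketed root search, `derive_thresholds()`).
* undefined by the model: the Gaussian Taylor curve has no finite zeros;
  Lactin-1 and Logan-6 approach zero only asymptotically at cold
  temperatures; the linear model never turns over.

Two forms in the source literature needed a decision. The four-parameter
beta function is implemented in its canonical form
$r(T) = c_m \frac{T_H - T}{T_H - T_{opt}}
\left(\frac{T - T_L}{T_{opt} - T_L}\right)^{(T_{opt} - T_L)/(T_H - T_{opt})}$,
whose peak is exactly $c_m$ at $T_{opt}$; published fits for both species
are reproduced by this form without an extra shape exponent. The Taylor
curve $r(T) = R_m \exp\!\big(-\tfrac12 ((T - T_{opt})/T_\sigma)^2\big)$
treats the third parameter as a Gaussian spread $T_\sigma$, not a
developmental zero, because the form has no finite zeros — even though
comparison tables in the literature often list that parameter in a
"$T_L$" row.

### Evaluation contract (clamping)

`evaluate_rate()` returns the raw formula value wherever it is real-valued
and non-negative, and exactly 0 where the formula is negative, complex
(e.g. $(T_H - T)^{1/m}$ above $T_H$), or outside explicit thresholds (the
Kontodimas parabola is positive below its own $T_L$, the Brière product is
positive again below 0 °C). Totalising the rate this way is what lets the
voltinism accumulator consume arbitrary daily temperatures without special
cases.

### A note on the Lactin family

The Lactin/Logan curves
$r(T) = e^{\rho T} - e^{\rho T_H - (T_H - T)/\Delta} (+\lambda)$ only
attain insect-like rate magnitudes where $\rho \approx 1/\Delta$ to within
about $10^{-4}$: the two exponentials nearly cancel and the small residual
is the rate. Two consequences shape the implementation. First, parameter
values rounded to two decimals (as printed in comparison tables) can
destroy the cancellation and imply rates an order of magnitude too large,
so thresholds derived from rounded Lactin parameters are unreliable — the
package derives them from whatever parameters it is given and leaves the
judgement to the screening step. Second, Latin-hypercube starts almost
never land on the cancellation ridge, so the multi-start fitter seeds
additional structural anchors with $\rho = 1/\Delta$ over a grid of
$\Delta$ and $T_H$ values for these three models.

## Fitting and model selection

`fit_linear()` is ordinary least squares of rate on temperature.
`fit_nonlinear()` minimises the residual sum of squares with bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`) from every start of a seeded
Latin-hypercube draw (default 200 starts) over the sampling box, plus
anchor starts (the shipped published parameter sets and the Lactin ridge
anchors). The default boxes place $T_L \in [-20, 20]$ °C,
$T_H \in [30, 50]$ °C and shape/rate parameters in wide positive boxes.
Residuals are computed on the *raw* formula (temperatures outside the real
domain predict rate 0): clamping negative values inside the optimiser
flattens the gradient and traps it, most visibly on the Lactin ridge. The
best-SSE converged start wins; ties go to the first found. Converged
parameter sets violating basic validity (non-positive scale parameters,
$T_L \ge T_H$) are discarded.

Fit quality uses the least-squares conventions
$S = \sqrt{SSE/(n-k)}$,
$AIC = n \ln(SSE/n) + 2(k+1)$,
$BIC = n \ln(SSE/n) + (k+1)\ln n$,
with the error variance counted as a parameter. Only differences matter;
`compare_models()` reports $\Delta AIC$/$\Delta BIC$ against the set
minimum, and the tests assert the deltas are invariant to any additive
constant in the convention. With five mean rates and four- or
five-parameter models the fits are near-saturated ($n - k \le 1$), so $S$
is reported as undefined when $n \le k$ rather than 0, and small
differences in the winning SSE move the deltas of *other* models
noticeably — a caveat to keep in mind when comparing delta values across
software.

Threshold screening (`screen_plausibility()`) marks each defined threshold
`+` (inside) or `-` (outside) against closed species-specific ranges, and
`.` when the model does not estimate it. The shipped defaults are
$T_L \in [6, 15]$, $T_{opt} \in [32, 34]$, $T_H \in [34, 36]$ °C for
*Te. remus* and $T_L \in [8, 15]$, $T_{opt} \in [30, 32]$,
$T_H \in [32, 33]$ °C for *T. foersteri*. The rule is applied strictly: a
value 0.05 °C outside a bound is `-`. Published mark tables assembled
partly by expert judgement can disagree with a strict rule near the
boundaries; the package deliberately keeps the reproducible rule.
`select_best()` is lexicographic: most `+` marks, then smallest
$\Delta AIC$, then fewest parameters, then alphabetical — fully
deterministic and order-invariant.

## Voltinism and exceedance

The daily development rate is the mean of the rates at the day's minimum
and maximum temperature. `annual_generations()` accumulates daily rates
from 1 January with an empty accumulator; a generation completes whenever
cumulative development reaches 1, the overshoot carrying forward. The
annual total (completed + residual fraction) therefore equals the plain
sum of daily rates — an identity the tests assert to $10^{-9}$. Years are
climatological (365 days, leap days dropped) and independent: no
development carries across years. Fractional totals are reported, not
floored. `count_exceedance()` counts days with $t_{min} < T_L$ (strict)
and days with $t_{max} \ge T_H$ (reach-or-exceed).

Climate input is a long table per cell (`doy`, `tmin`, `tmax`).
`build_climatology()` averages each day-of-year over years (gaps are a
hard error naming the missing cell-years). Warming uses the delta-change
method: `compute_delta()` takes per-cell current and future mean annual
temperatures — the mean over days of $(t_{min}+t_{max})/2$, since
"mean annual temperature" is otherwise underdefined — averaging multiple
projections into a consensus, and `apply_delta()` adds each cell's delta
uniformly to every day's `tmin` and `tmax` (no monthly disaggregation).
Both the current and future mean fields are explicit inputs, so any
baseline convention can be expressed by the caller.

## Synthetic data

Two generators make the pipeline testable without external downloads.

`gen_dev_data()` emulates a constant-temperature development trial: around
the true curve of a chosen model, replicate development *times* are drawn
as $t = (1/r)(1 + \varepsilon)$, $\varepsilon \sim N(0, cv)$ —
multiplicative noise on time, which is what a rearing trial measures. The
default design is the study's (five chambers 15–35 °C, 20 replicates);
the default $cv = 0.05$ is loosely calibrated to reported standard errors
(1–5% of the means). Temperatures where the true rate is non-positive
yield no emergence and are censored from the rates.

`gen_climate_grid()` emulates the study region's daily grids: per cell,
$t_{mid}(d) = \mu + A\cos(2\pi(d - d_{peak})/365) + \epsilon_d$ with
$t_{min}/t_{max}$ half the diurnal range below/above. Defaults: annual
means drawn over 12–24 °C (cold highlands to warm northwest), amplitude
6 °C, diurnal range 10 °C, day-to-day noise sd 1.5 °C, warmest day near
15 January (southern hemisphere). Cells are independent — no spatial
correlation, no autocorrelated weather, no heat waves — and the diurnal
range is constant. Passing tests on these grids therefore demonstrates the
*arithmetic* of voltinism projection, not fidelity to interpolated
station data; real-grid magnitudes (e.g. absolute generation counts per
municipality) are outside what the synthetic grid can certify.

## Problem sizes and numerical choices

* $T_{opt}$ grid step 0.01 °C, refinement tolerance $10^{-8}$; reported
  thresholds conventionally rounded to 2 decimals.
* Root searches scan at 0.25 °C over $[-60, 80]$ °C and bracket with
  `uniroot` (tolerance $10^{-9}$); a failed bracket returns an undefined
  threshold, never an error.
* Multi-start defaults: 200 Latin-hypercube starts for headline fits;
  the Monte-Carlo recovery study uses 100 replicates per model with 50
  starts each, and the recovery property tests 25 replicates with 40
  starts — sizes chosen so the full suite stays interactive while the
  pass criteria (median threshold error < 1.5 °C; ≥ 80% of replicates
  within 1.5 °C) keep comfortable margins.
* Recovery trials place their 8 test temperatures from $T_L + 2$ °C up to
  $T_H - 0.5$ °C. Sampling the falling limb is essential: for curves with
  a steep upper cut-off (Performance-2, Shi) the data carry almost no
  information on $T_H$ unless temperatures approach it, and stopping 2 °C
  short leaves $T_H$ unidentified.
* Seeds: every stochastic step (Latin-hypercube draws, synthetic noise)
  takes an explicit integer seed; identical seeds give identical output.

## Known limitations

* Fitting uses mean rates, one point per temperature — no replicate-level
  or weighted likelihood, no bootstrap intervals for thresholds.
* The development data shipped cover *Te. remus*; for *T. foersteri* only
  published parameter sets are included, so that species' fits cannot be
  re-derived from raw data here.
* Near-saturated fits ($n - k \le 1$) make AIC comparisons fragile;
  the selection rule's primary criterion (plausible thresholds) partly
  compensates, but adding test temperatures is the real cure.
* No humidity/photoperiod covariates, no diurnal sine interpolation for
  degree-days, no host–parasitoid synchrony.
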