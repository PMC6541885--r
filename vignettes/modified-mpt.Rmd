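---
title: "Nighttime CO2 flux filtering on hilly terrain: the modified moving point test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nighttime CO2 flux filtering on hilly terrain: the modified moving point test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(mptflux)
```

## The problem

Eddy-covariance towers measure the net ecosystem exchange (NEE) of CO2 as
the sum of the turbulent eddy flux and the storage flux below the sensor.
That sum equals the true exchange only when advection is negligible.  At
night over hilly terrain two things go wrong.  First, under weak
turbulence (low friction velocity u\*) the measurement systematically
underestimates the efflux; the classical remedy is to reject nighttime
records below a u\* threshold.  Second, downslope **drainage flow** can
remove respired CO2 below the sensor even when u\* measured above the
canopy is high — the measured flux then sits near zero at mild
temperatures, and no u\* filter can see it.  Because nighttime data
calibrate the ecosystem-respiration (ER) model used for gap-filling and
for partitioning NEE into ER and gross primary productivity (GPP), both
biases propagate into annual carbon budgets.

`mptflux` combines an objective u\*-threshold detector (the moving point
test) with a time-window test for drainage, plus the surrounding
machinery: temperature-response fitting, gap-filling, partitioning,
baseline methods, and a synthetic generator with known truth.

## Model and procedure

### Temperature response

Nighttime ER is modelled with the Lloyd–Taylor equation
$$ER(T_a) = R_{ref}\,\exp\!\left(E_0\left[\frac{1}{T_{ref}-T_0}
  - \frac{1}{T_a-T_0}\right]\right),$$
with $T_{ref} = 10$ °C and $T_0 = -46.02$ °C fixed.  $E_0$ carries units
of temperature (°C), which the closed form requires, although it is
often printed with inverse-temperature units.  $E_0$ is held constant
per site-year and estimated from short-term windows (15 days, stepped 5
days; windows accepted with at least 6 points, a temperature span of at
least 5 °C and a fitted $E_0 \in [30, 450]$; the site-year value is the
mean of the three accepted fits with the smallest relative standard
error, falling back to the literature default 309 °C with a warning when
nothing is accepted).  The short-window design keeps slow confounders
(soil moisture, phenology) out of the temperature sensitivity; their
effect is absorbed instead by $R_{ref}$, refitted in a 30-day window
stepped every 5 days and interpolated to daily values.

Two-parameter fits use a Levenberg–Marquardt least-squares solver
(start: $R_{ref}$ = mean flux, $E_0 = 309$; bounds $R_{ref} \in
(0, 100]$, $E_0 \in [10, 600]$; convergence reported, never thrown).
One-parameter fits with $E_0$ fixed reduce to closed-form linear least
squares.  Confidence bands come from first-order (delta-method) error
propagation with Student-t quantiles; the *prediction* variant adds the
residual standard deviation in quadrature and is what the
underestimation filter uses — a mean-response band would reject half of
the well-behaved observations.

### The moving point test

Per three-month period (day-of-year 1–90, 91–181, 182–273, 274–365/366,
membership by the interval-end day of year), nighttime fluxes inside the
current thresholds $(u^*_L, u^*_H)$ — initialized to $(0, 9999)$ — are
normalized by the fitted ER, cleaned with a single-pass 3σ rule, and
sorted by ascending u\* (ties broken by timestamp).  Moving samples of
$n = 25$ consecutive-u\* points slide from the highest u\* downward one
point per step, and each sample mean is Welch-tested against the mean of
all in-threshold records at $\alpha_{MPT} = 0.1$.

**The trigger rule.**  A single significant sample cannot be the trigger:
with roughly 2000 nighttime records per period the scan performs ~80
effectively independent tests, so at $\alpha = 0.1$ *some* sample is
significant in essentially every period even without any u\* dependence,
and a first-hit rule would place thresholds near the top of the u\*
distribution.  The scan therefore (1) tests one-sidedly for a *deficit*
(the moving mean below the reference mean — the direction advection
losses take), and (2) triggers only on a *sustained run* of at least
$2n$ consecutive significant samples, i.e. the deficit must persist
while the moving sample turns over completely twice.  Under the null
this controls the per-scan false-trigger rate to a few percent (the
no-dependence scenario returns the open interval $(0, 9999)$ in ~95 % of
seeds), while an injected suppression of 0.3 is detected in every scan
with the candidate threshold — the median u\* of the run's first
sample — landing on the injected value to within one bin.  A run starting at the very first (highest-u\*) sample marks an
anomalous top stratum and updates $u^*_H$ instead; this first-sample
rule applies in every outer round, so an upper threshold can tighten
after one has been found.  Symmetric consequences of the one-sided
design: a flux *excess* is never a trigger, and deficits spanning fewer
than about $2n$ low-u\* points are not detectable.

After each update the ER model is refitted inside the new thresholds and
the scan repeats; thresholds only move inward; convergence is a full
scan with no trigger, capped at 50 outer rounds.  The reference sample
includes the moving sample's own points (full overlap), which is
immaterial at these sample-size ratios.

### Two time windows and the drainage decision

On drainage-affected sites the flux is trustworthy only near the evening
peak, before the drainage layer establishes.  The night is therefore
split at the peak of the median diurnal NEE cycle (searched between
15:00 and 22:00 local; ties to the earliest slot; a boundary peak
warns): window 1 spans $[t_{peak} - 1\,h,\ t_{peak} + 2\,h]$ — the
asymmetry reflects that drainage develops *after* the peak — and window
2 is the remainder of the night through the morning, wrapping midnight.
Rare nighttime records before window 1 are treated as window 1
(pre-peak, pre-drainage).  The moving point test runs independently per
window.

Drainage at midnight is then judged by Welch-comparing the windows'
u\*-filtered fluxes at $\alpha_{drain} = 0.05$ (separate from
$\alpha_{MPT}$; the conventional 95 % confidence level), both
normalized by **one shared** temperature response fitted to the pooled
retained records of the two windows.  A window-specific fit would not
do: a three-hour evening window barely constrains $E_0$, and
extrapolating such a fit to the colder late night injects a systematic
difference that inflates the null rejection rate several-fold; with the
shared fit, drainage-free scenarios are essentially never flagged.  The
decision is one-sided: only a
*lower* window-2 mean is drainage; a higher one is not.  Fewer than 10
retained records in either window make the outcome "undetermined",
treated as negligible with a warning.

If drainage is significant, every nighttime window-2 record is rejected
(reason `second_window_drainage`) and window 1 is filtered by its own
thresholds; otherwise each window is filtered by its own thresholds
(`low_ustar` / `high_ustar`).  A window whose threshold search fails
falls back to the fixed 0.3 m s⁻¹ threshold and flags the period.

### Gap-filling, partitioning, budgets

Rejected and missing nighttime records are replaced by the temperature
response evaluated at the record's air temperature (daily $R_{ref}$,
site-year $E_0$); air-temperature gaps are interpolated up to 3 h, and
records that still cannot be filled are counted and reported, never
dropped.  Daytime ER is the same extrapolation at daytime temperature;
GPP = ER − NEE with nighttime GPP pinned to zero, so residual night
noise stays in NEE rather than leaking into GPP.  Annual sums convert
mg CO2 m⁻² s⁻¹ over 1800-s intervals with 12.011/44.009 g C per g CO2;
NEE = ER − GPP holds exactly because all three are summed along the same
path.  Daytime NEE gaps are out of scope and must be pre-filled; the
budget function refuses unresolved records.

### Baselines

Fixed-threshold friction-velocity filtering (0.3 m s⁻¹, night only),
the light-response-curve method (daily Michaelis–Menten fits in 30-day
windows; the zero-light intercept is the daytime-ER observation, paired
with the window's mean daytime temperature), and the sunset-peak van
Gorsel variant (the 30-day median-diurnal-cycle peak near sunset, paired
with the peak slot's median temperature).  For the latter two the
nighttime record filter is the one-sided 95 % prediction-band
underestimation rule.

## The synthetic test bed

`generate_flux()` builds half-hourly series with known truth: a diel
temperature cycle (amplitude 6 °C, peak 14:00) over a weak seasonal
cycle (amplitude 8 °C), Lloyd–Taylor respiration ($R_{ref} = 0.2$
mg CO2 m⁻² s⁻¹, $E_0 = 250$ °C), a solar-shaped radiation course
(06–18 h, peak 600 W m⁻²) driving Michaelis–Menten uptake, and lognormal
u\* (night median 0.25, day 0.4 m s⁻¹, σ_log = 0.5) so both sides of the
threshold are populated.  Suppression is purely statistical, as the
method sees it: the measured night flux is multiplied by
`suppression_factor` below the threshold, by `suppression_factor_w2`
inside a fixed post-sunset clock window (default from 20:30) when
drainage is enabled, and by `anomaly_factor` above `anomaly_ustar` for
the top-stratum scenario (set at 0.5 m s⁻¹, the top ~8 % of the night
distribution, so the anomalous stratum comfortably exceeds the sustained
run length).  Noise is mean-one multiplicative lognormal (σ = 0.2, so
noisy scenarios stay unbiased in the mean) plus a small additive term
(σ = 0.005 mg CO2 m⁻² s⁻¹).  The standard scenarios (90 days each) are
`no_dependence`, `threshold_only` (×0.3 below 0.25 m s⁻¹),
`threshold_plus_drainage`, and `high_ustar_anomaly`.

What the generator does *not* emulate: physical drainage dynamics,
storage-flux structure, weather (clouds, fronts, rain), heteroscedastic
instrument dropouts, or seasonal changes in the true $R_{ref}$ and light
response.  Passing tests therefore demonstrate that the statistics of
the method work under its own assumptions — clean suppression geometry
and stationary parameters — not that any particular field dataset is
handled correctly.

```{r example}
sim <- generate_flux(scenario_library(seed = 42)$threshold_plus_drainage)
res <- run_modified_mpt(sim$series)
res
```

```{r diurnal, fig.height = 3}
plot_diurnal_cycle(median_diurnal_cycle(sim$series), search_window = c(15, 22))
```

## Numerical choices and degenerate inputs

* Night is `rg < 10` W m⁻² (strict; configurable): the community default
  needing no site coordinates.  Missing radiation inherits the nearest
  same-time-of-day flag.
* Timestamps label the interval **end**, local standard time, no DST —
  documented, not enforced.  On disk, missing is −9999; in memory,
  explicit `NA` plus a `qc` state, so sentinel arithmetic cannot happen.
* Zero-variance Welch comparisons: equal means give p = 1, unequal p = 0.
  A zero standard deviation retains everything in the 3σ rule.
* u\* ties are broken by timestamp; scan results are invariant to input
  row order.
* Solver tolerances are set tight (1e-14) so noiseless recovery tests
  are limited by the optimizer, not the configuration.
* Problem sizes in the checks were chosen for a desk-scale test bed:
  90-day periods (~2100 nighttime records) for threshold and drainage
  rates at 50 seeds, 2000-point fits for parameter recovery, and
  full-year (17 520-record) runs for budget comparisons at 30–50 seeds.

## Known limitations

* The drainage decision inherits the evening-peak location.  When noise
  moves the detected peak late, window 1 can overlap the true drainage
  onset and the test loses power; measured detection is ~90–95 % at
  suppression 0.3, with misses concentrated in late-peak draws.
* An `E0` calibrated on window-1-only data (after a drainage rejection)
  rests on a short nightly temperature span; an annual ER error of a few
  percent remains even when the filter is correct (about 1 % on the
  identity scenario, larger when drainage rejection leaves only the
  evening window for calibration).
* The one-sided scan cannot see flux *excess* anomalies, and deficits
  narrower than twice the moving-sample size are invisible by design.
* Thresholds are strictly per period and per window; no pooling across
  seasons, sites or years.
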