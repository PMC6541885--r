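# mptflux

Nighttime eddy-covariance CO₂ fluxes measured over hilly or complex
terrain are systematically biased: under weak turbulence (low friction
velocity u\*) the tower misses part of the efflux, and downslope **drainage
flow** can carry respired CO₂ away below the sensor so that the measured
flux is near zero even when u\* is high.  Both biases corrupt ecosystem
respiration (ER), and through it the partitioning of net ecosystem
exchange (NEE) into ER and gross primary productivity (GPP).

`mptflux` implements the **modified moving point test** for flux tower
data processing: an objective, per-period friction-velocity threshold
detector combined with a two-time-window test for midnight drainage.  It
is written for micrometeorologists processing half-hourly flux data, and
for method work on synthetic data with known truth.

## The method

**Temperature response.**  Nighttime ER is modelled with the Lloyd–Taylor
equation

    ER(Ta) = R_ref · exp( E0 · [ 1/(T_ref − T0) − 1/(Ta − T0) ] )

with T_ref = 10 °C and T0 = −46.02 °C.  E0 is held constant per site-year,
estimated from short-term (15-day) windows so that slow drivers (soil
moisture, phenology) do not contaminate the temperature sensitivity;
R_ref is re-estimated in a 30-day window stepped every 5 days.

**Moving point test (MPT).**  Per three-month period, nighttime fluxes are
normalized by the fitted ER, 3σ-outliers removed, and records sorted by
u\*.  Moving samples of n = 25 consecutive-u\* points slide from the
highest u\* downward; each sample's mean is Welch-tested (α = 0.1) against
the mean of all records inside the current thresholds.  A *sustained* run
of significant deficits marks the onset of flux suppression: the lower
threshold u\*_L is set to the median u\* of the first deficient sample (or
the upper threshold u\*_H if the deficit starts in the topmost stratum),
the ER fit is repeated inside the new thresholds, and the loop continues
until a clean scan.  `9999` is the sentinel for "no upper threshold".

**The modification for drainage.**  The night is split at the evening NEE
peak (from the median diurnal cycle) into window 1 (`[peak − 1 h, peak +
2 h]`, before drainage develops) and window 2 (the rest of the night).
The MPT runs in each window separately; then the u\*-filtered fluxes of
both windows, normalized by one shared ER fit, are Welch-compared.  If
window 2 is significantly *lower* (α = 0.05), midnight drainage is
declared and **all** window-2 nighttime records are rejected.  Rejected
and missing nighttime records are refilled from the temperature response,
daytime ER is extrapolated from the nighttime relationship, and
GPP = ER − NEE with night GPP pinned to zero.

Three baselines are included for comparison: fixed-threshold
friction-velocity filtering (FVF, default 0.3 m s⁻¹), the
light-response-curve intercept (LRC), and the sunset-peak van Gorsel
variant (VGF), the latter two with a 95 % prediction-band
underestimation filter.

## Worked example

Ninety synthetic winter days with a true u\* threshold of 0.25 m s⁻¹
(suppression ×0.3 below it) and post-sunset drainage (×0.3 after ~20:30):

```r
library(mptflux)
cfg <- scenario_library(seed = 42)$threshold_plus_drainage
sim <- generate_flux(cfg)
run_modified_mpt(sim$series)
#> Modified moving point test, DOY 1-91
#>   evening peak at 18.0 h; window 1 = [17.0, 20.0] h
#>   window 1: u*L = 0.246, u*H = 9999
#>   window 2: u*L = 0.249, u*H = 9999
#>   drainage at midnight: significant (p = 6.37e-27)
```

Both windows recover the injected threshold to within 0.004 m s⁻¹, and
the drainage suppression of window 2 is detected.  On a full year the
corrected annual respiration lands close to the generator's truth where
the fixed 0.3 m s⁻¹ filter — which trusts the drained high-u\* fluxes —
misses badly:

```r
year <- generate_flux(synth_config(seed = 42, n_days = 365,
                                   ustar_threshold = 0.25,
                                   suppression_factor = 0.3,
                                   drainage_enabled = TRUE))
compare_methods(year$series, methods = c("mpt", "fvf"))[, c("method", "nee", "gpp", "er")]
#>   method        nee      gpp       er
#> 1    mpt   91.42458 1963.389 2054.813
#> 2    fvf -109.69397 1422.092 1312.398
```

The generator's true annual ER here is 2153.9 g C m⁻²: the modified MPT
recovers it to −4.6 %, the fixed filter to −39 %.  (NEE/GPP/ER in
g C m⁻² yr⁻¹; negative NEE = net uptake.)

A 12-day synthetic sample in the package's CSV dialect (−9999 missing
sentinel, interval-end timestamps) ships under
`inst/extdata/synthetic_halfhourly_sample.csv`; read it with
`read_halfhourly_csv()`.  A command-line front end for
simulate/thresholds/correct lives at `inst/cli/fluxmpt.R`.

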