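#' Configuration of the synthetic half-hourly flux generator
#'
#' Describes a synthetic site-period with known truth: a diel (and weak
#' seasonal) air-temperature cycle driving Lloyd-Taylor respiration, a
#' solar-shaped radiation course driving Michaelis-Menten uptake,
#' lognormal friction velocity with a nighttime shift toward low values
#' (so both sides of the threshold are populated), u*-dependent
#' suppression of the measured nighttime flux below a known threshold, an
#' optional post-sunset drainage window in which the measured flux is
#' additionally suppressed regardless of u* (the statistical signature of
#' downslope drainage), an optional deficit in the topmost u* stratum, and
#' mean-one multiplicative lognormal plus additive Gaussian noise.
#'
#' @param seed RNG seed; a generated series is fully reproducible from it.
#' @param n_days Number of days (>= 7; default 90, one detection period).
#' @param year Calendar year of the first day (default 2009).
#' @param r_ref,e0 True Lloyd-Taylor parameters (defaults 0.2 mg CO2
#'   m-2 s-1 and 250 deg C).
#' @param ta_mean,ta_amplitude Mean and diel amplitude of air temperature,
#'   deg C (defaults 12 and 6; the diel peak is at 14:00).
#' @param ta_seasonal_amplitude Seasonal amplitude, deg C (default 8,
#'   minimum in late January).
#' @param rg_peak Noon shortwave peak, W m-2 (default 600; fixed 06-18 h
#'   daylight, no solar geometry).
#' @param alpha_qy,a_max True light-response parameters (defaults 0.002
#'   mg CO2 m-2 s-1 per W m-2 and 1.2 mg CO2 m-2 s-1).
#' @param ustar_median_night,ustar_median_day,ustar_sdlog Lognormal u*
#'   parameters (defaults 0.25, 0.40 m s-1 and 0.5).
#' @param ustar_threshold True friction-velocity threshold, m s-1
#'   (default 0.25).
#' @param suppression_factor Multiplier on the measured nighttime flux
#'   when u* is below the threshold (default 1 = no dependence).
#' @param drainage_enabled Logical; inject a post-sunset drainage window.
#' @param drainage_offset_h Start of the drainage window, hours after the
#'   18:00 sunset (default 2.5, i.e. from 20:30 to the end of the night).
#' @param suppression_factor_w2 Multiplier applied inside the drainage
#'   window regardless of u* (default 0.3).
#' @param anomaly_ustar Optional u* above which nighttime fluxes are
#'   multiplied by `anomaly_factor` (a deficit in the top stratum;
#'   default `NA` = off).
#' @param anomaly_factor Multiplier above `anomaly_ustar` (default 0.3).
#' @param noise_mult_sd Log-scale sd of the mean-one multiplicative
#'   lognormal noise (default 0.2).
#' @param noise_add_sd Additive Gaussian noise sd, mg CO2 m-2 s-1
#'   (default 0.005).
#' @param missing_frac Fraction of records whose NEE is removed
#'   (default 0).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, n_days = 90, year = 2009,
                         r_ref = 0.2, e0 = 250,
                         ta_mean = 12, ta_amplitude = 6,
                         ta_seasonal_amplitude = 8,
                         rg_peak = 600, alpha_qy = 0.002, a_max = 1.2,
                         ustar_median_night = 0.25, ustar_median_day = 0.4,
                         ustar_sdlog = 0.5,
                         ustar_threshold = 0.25, suppression_factor = 1,
                         drainage_enabled = FALSE, drainage_offset_h = 2.5,
                         suppression_factor_w2 = 0.3,
                         anomaly_ustar = NA_real_, anomaly_factor = 0.3,
                         noise_mult_sd = 0.2, noise_add_sd = 0.005,
                         missing_frac = 0) {
  stopifnot(n_days >= 7, suppression_factor >= 0, suppression_factor <= 1,
            suppression_factor_w2 >= 0, suppression_factor_w2 <= 1,
            missing_frac >= 0, missing_frac < 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic flux series with known truth
#'
#' Builds the half-hourly series described by a [synth_config()]:
#' true respiration `er_true = lloyd_taylor(ta)`, true uptake `gpp_true`
#' from the light response of `rg`, `nee_true = er_true - gpp_true`
#' (exactly, record by record); the measured NEE is the true NEE times the
#' applicable suppression factors (below-threshold u*, drainage window,
#' top-stratum anomaly), times mean-one lognormal noise, plus additive
#' noise; then missingness.  Identical seeds give identical output.
#'
#' @param config A [synth_config()].
#' @return A list with `series` (canonical flux series tibble, night
#'   flagged) and `truth` (tibble with `timestamp`, `er_true`, `gpp_true`,
#'   `nee_true`, `suppressed`, `in_drainage_window`, `in_anomaly`).
#' @export
generate_flux <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  n <- cfg$n_days * 48L
  start <- as.POSIXct(sprintf("%d-01-01 00:30", cfg$year), tz = "UTC")
  ts <- start + 1800 * (seq_len(n) - 1)
  tod <- interval_tod(ts)
  doy <- lubridate::yday(ts)

  ta <- cfg$ta_mean +
    cfg$ta_seasonal_amplitude * -cos(2 * pi * (doy - 15) / 365) +
    cfg$ta_amplitude * cos(2 * pi * (tod - 14) / 24)
  rg <- ifelse(tod > 6 & tod < 18,
               cfg$rg_peak * sin(pi * (tod - 6) / 12), 0)
  is_night <- rg < 10

  er_true <- lloyd_taylor(ta, cfg$r_ref, cfg$e0)
  gpp_true <- lrc_gpp(rg, cfg$alpha_qy, cfg$a_max)
  nee_true <- er_true - gpp_true

  withr::with_seed(cfg$seed, {
    ustar <- stats::rlnorm(n,
                           meanlog = ifelse(is_night,
                                            log(cfg$ustar_median_night),
                                            log(cfg$ustar_median_day)),
                           sdlog = cfg$ustar_sdlog)
    suppressed <- is_night & ustar < cfg$ustar_threshold
    in_drain <- if (cfg$drainage_enabled) {
      is_night & circ_delta(tod, 18 + cfg$drainage_offset_h) <
        circ_delta(12, 18 + cfg$drainage_offset_h)
    } else {
      rep(FALSE, n)
    }
    in_anom <- if (is.finite(cfg$anomaly_ustar)) {
      is_night & ustar > cfg$anomaly_ustar
    } else {
      rep(FALSE, n)
    }
    factor <- ifelse(suppressed, cfg$suppression_factor, 1) *
      ifelse(in_drain, cfg$suppression_factor_w2, 1) *
      ifelse(in_anom, cfg$anomaly_factor, 1)
    s <- cfg$noise_mult_sd
    mult <- exp(stats::rnorm(n, -s^2 / 2, s))
    nee <- nee_true * factor * mult + stats::rnorm(n, 0, cfg$noise_add_sd)
    missing <- rep(FALSE, n)
    if (cfg$missing_frac > 0) {
      missing <- stats::runif(n) < cfg$missing_frac
      nee[missing] <- NA_real_
    }
  })

  series <- tibble::tibble(
    timestamp = ts, nee = nee, ustar = ustar, ta = ta, rg = rg,
    qc = ifelse(is.na(nee), "missing", "observed"),
    is_night = is_night
  )
  truth <- tibble::tibble(
    timestamp = ts, er_true = er_true, gpp_true = gpp_true,
    nee_true = nee_true, suppressed = suppressed,
    in_drainage_window = in_drain, in_anomaly = in_anom
  )
  list(series = series, truth = truth)
}

lrc_gpp <- function(rg, alpha_qy, a_max) {
  ifelse(rg > 0, (alpha_qy * rg * a_max) / (alpha_qy * rg + a_max), 0)
}

#' Named scenario configurations
#'
#' The standard test-bed scenarios: `no_dependence` (no u* suppression, no
#' drainage), `threshold_only` (suppression 0.3 below u* = 0.25 m s-1),
#' `threshold_plus_drainage` (additionally, fluxes in the post-sunset
#' drainage window suppressed to 0.3 regardless of u*, emulating
#' near-zero midnight fluxes at mild temperatures despite u* above the
#' traditional threshold), and `high_ustar_anomaly` (a flux deficit
#' confined to the topmost u* stratum, u* > 0.6 m s-1).
#'
#' @param seed Seed stored in every configuration.
#' @param n_days Days per scenario (default 90).
#' @param ... Further overrides passed to every [synth_config()].
#' @return A named list of `synth_config` objects.
#' @export
scenario_library <- function(seed = 1, n_days = 90, ...) {
  base <- function(...) synth_config(seed = seed, n_days = n_days, ...)
  list(
    no_dependence = base(suppression_factor = 1, ...),
    threshold_only = base(ustar_threshold = 0.25, suppression_factor = 0.3,
                          ...),
    threshold_plus_drainage = base(ustar_threshold = 0.25,
                                   suppression_factor = 0.3,
                                   drainage_enabled = TRUE,
                                   suppression_factor_w2 = 0.3, ...),
    high_ustar_anomaly = base(suppression_factor = 1, anomaly_ustar = 0.5,
                              anomaly_factor = 0.3, ...)
  )
}
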