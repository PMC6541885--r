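#' Fixed-threshold friction-velocity filter
#'
#' The classical baseline: nighttime records with u* below a fixed
#' threshold are rejected; daytime records are never filtered (the daytime
#' atmosphere is unstable and well mixed).  Nighttime records with missing
#' u* are rejected with reason `"missing_ustar"`.  The mask is monotone in
#' the threshold: raising it never un-rejects a record.
#'
#' @param series A flux series with `is_night`.
#' @param threshold Fixed u* threshold, m s-1 (default 0.3, the site
#'   baseline for these hilly-terrain forests).
#' @return A mask tibble with `timestamp`, `keep`, `reason`.
#' @export
fvf_filter <- function(series, threshold = 0.3) {
  if (!"is_night" %in% names(series)) series <- flag_night(series)
  nightly <- series$is_night & series$qc == "observed"
  low <- nightly & !is.na(series$ustar) & series$ustar < threshold
  miss <- nightly & is.na(series$ustar)
  tibble::tibble(
    timestamp = series$timestamp,
    keep = !(low | miss),
    reason = dplyr::case_when(low ~ "low_ustar", miss ~ "missing_ustar",
                              TRUE ~ NA_character_)
  )
}

#' Michaelis-Menten light response
#'
#' Rectangular-hyperbola NEE model of the daytime flux,
#' \deqn{NEE = R_{LRCd} - \frac{\alpha Q_t A_{max}}{\alpha Q_t + A_{max}},}
#' whose zero-light intercept `r_lrcd` estimates the mean daytime
#' ecosystem respiration.  Strictly decreasing in `qt`, bounded below by
#' `r_lrcd - a_max`.
#'
#' @param qt Incident shortwave radiation, W m-2 (>= 0).
#' @param r_lrcd Mean daytime respiration (y-intercept), mg CO2 m-2 s-1.
#' @param alpha_qy Apparent quantum yield, mg CO2 m-2 s-1 per W m-2.
#' @param a_max Canopy photosynthetic capacity, mg CO2 m-2 s-1.
#' @return Modelled NEE, mg CO2 m-2 s-1.
#' @export
lrc_response <- function(qt, r_lrcd, alpha_qy, a_max) {
  r_lrcd - (alpha_qy * qt * a_max) / (alpha_qy * qt + a_max)
}

#' Fit the light response curve to daytime records
#'
#' Nonlinear least squares of [lrc_response()] on daytime (radiation, NEE)
#' pairs.
#'
#' @param data Data frame with `rg` and `nee` (daytime records; rows with
#'   missing values are dropped).
#' @param min_n Minimum usable pairs (default 50).
#' @return A list with `r_lrcd`, `alpha_qy`, `a_max`, `n_fit`, `converged`.
#' @export
fit_lrc <- function(data, min_n = 50) {
  keep <- !is.na(data$rg) & !is.na(data$nee)
  df <- data.frame(qt = data$rg[keep], y = data$nee[keep])
  if (nrow(df) < min_n) {
    abort(sprintf("fit_lrc: %d usable pairs, need >= %d", nrow(df), min_n),
          class = "mptflux_insufficient_data")
  }
  start <- list(r_lrcd = max(stats::quantile(df$y, 0.95), 0.01),
                alpha_qy = 0.002,
                a_max = max(diff(range(df$y)), 0.1))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ r_lrcd - (alpha_qy * qt * a_max) / (alpha_qy * qt + a_max),
      data = df, start = start,
      lower = c(r_lrcd = -10, alpha_qy = 1e-6, a_max = 1e-3),
      upper = c(r_lrcd = 10, alpha_qy = 1, a_max = 50),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(r_lrcd = NA_real_, alpha_qy = NA_real_, a_max = NA_real_,
                n_fit = nrow(df), converged = FALSE))
  }
  cf <- coef(fit)
  list(r_lrcd = cf[["r_lrcd"]], alpha_qy = cf[["alpha_qy"]],
       a_max = cf[["a_max"]], n_fit = nrow(df), converged = TRUE)
}

#' Daily daytime respiration from moving-window light-response fits
#'
#' Fits the light response curve in a centered moving window (default 30
#' days) stepped daily over daytime records, and returns the daily
#' intercept `r_lrcd` together with the window's mean daytime temperature
#' (the pairing used when these daily values feed a temperature-response
#' fit).  Days whose window fit fails are interpolated from neighboring
#' days.
#'
#' @param series A flux series with `is_night`.
#' @param window_days Moving-window length in days (default 30).
#' @param min_n Minimum daytime records per window (default 50).
#' @return A tibble with `date`, `r_lrcd`, `alpha_qy`, `a_max`, `ta`,
#'   `n_fit`, `interpolated`.
#' @export
lrc_daily <- function(series, window_days = 30, min_n = 50) {
  if (!"is_night" %in% names(series)) series <- flag_night(series)
  day <- series[!series$is_night & series$qc == "observed" &
                  !is.na(series$rg) & !is.na(series$nee), ]
  if (!nrow(day)) {
    abort("lrc_daily: no usable daytime records",
          class = "mptflux_insufficient_data")
  }
  dates <- seq(as.Date(min(series$timestamp - 1)),
               as.Date(max(series$timestamp - 1)), by = 1)
  ddate <- as.Date(day$timestamp - 1)
  rows <- purrr::map_dfr(dates, function(d) {
    in_w <- ddate >= d - window_days / 2 & ddate < d + window_days / 2
    sub <- day[in_w, ]
    out <- tibble::tibble(date = d, r_lrcd = NA_real_, alpha_qy = NA_real_,
                          a_max = NA_real_, ta = NA_real_,
                          n_fit = nrow(sub), interpolated = TRUE)
    if (nrow(sub) < min_n) return(out)
    fit <- tryCatch(fit_lrc(sub, min_n = min_n),
                    mptflux_insufficient_data = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(out)
    out$r_lrcd <- fit$r_lrcd
    out$alpha_qy <- fit$alpha_qy
    out$a_max <- fit$a_max
    out$ta <- mean(sub$ta, na.rm = TRUE)
    out$interpolated <- FALSE
    out
  })
  if (all(rows$interpolated)) {
    abort("lrc_daily: no window produced a light-response fit",
          class = "mptflux_insufficient_data")
  }
  for (col in c("r_lrcd", "alpha_qy", "a_max", "ta")) {
    rows[[col]] <- zoo::na.approx(rows[[col]], x = as.numeric(rows$date),
                                  na.rm = FALSE, rule = 2)
  }
  rows
}

#' Daily sunset-peak respiration (van Gorsel variant)
#'
#' For each day, computes the median diurnal cycle over a centered moving
#' window (default 30 days) and takes the sunset-window peak of that cycle
#' as the day's respiration observation `r_max` (the flux near sunset,
#' before drainage develops, taken to represent the true efflux), paired
#' with the median air temperature of the peak slot.
#'
#' @param series A flux series.
#' @param window_days Moving-window length in days (default 30; must cover
#'   at least 7 days of data).
#' @param search_window Peak search window, clock hours (default
#'   `c(15, 22)`).
#' @return A tibble with `date`, `r_max`, `t_peak`, `ta`.  Days where no
#'   peak can be found are absent.
#' @export
vgf_rmax <- function(series, window_days = 30, search_window = c(15, 22)) {
  dates <- seq(as.Date(min(series$timestamp - 1)),
               as.Date(max(series$timestamp - 1)), by = 1)
  sdate <- as.Date(series$timestamp - 1)
  tod <- interval_tod(series$timestamp)
  purrr::map_dfr(dates, function(d) {
    in_w <- sdate >= d - window_days / 2 & sdate < d + window_days / 2
    sub <- series[in_w, ]
    res <- tryCatch({
      cyc <- median_diurnal_cycle(sub)
      tp <- withCallingHandlers(find_sunset_peak(cyc, search_window),
                                warning = function(w) invokeRestart("muffleWarning"))
      slot <- sub[tod[in_w] == tp & sub$qc == "observed", ]
      tibble::tibble(date = d,
                     r_max = cyc$median_nee[cyc$tod == tp],
                     t_peak = tp,
                     ta = median(slot$ta, na.rm = TRUE))
    }, mptflux_insufficient_data = function(e) e)
    if (inherits(res, "condition")) {
      if (grepl("days of data", conditionMessage(res))) {
        abort(conditionMessage(res), class = "mptflux_insufficient_data")
      }
      return(NULL)
    }
    res
  })
}

#' Confidence-interval underestimation filter
#'
#' Rejects nighttime observations that fall below the lower bound of the
#' temperature-response model's 95% band at the record's temperature —
#' fluxes underestimated beyond what the model and its residual scatter
#' allow (the prediction band: a mean-response band would cut half of the
#' well-behaved observations).  One-sided: only underestimation is
#' filtered.
#'
#' @param series A flux series with `is_night`.
#' @param fit A [fit_trf()] object with standard errors.
#' @param level Band level (default 0.95).
#' @return A mask tibble with `timestamp`, `keep`, `reason`
#'   (`"ci_underestimate"`).
#' @export
ci_underestimation_filter <- function(series, fit, level = 0.95) {
  if (!"is_night" %in% names(series)) series <- flag_night(series)
  nightly <- series$is_night & series$qc == "observed" &
    !is.na(series$nee) & !is.na(series$ta)
  keep <- rep(TRUE, nrow(series))
  if (any(nightly)) {
    band <- trf_confidence_band(fit, series$ta[nightly], level = level,
                                interval = "prediction")
    keep[nightly] <- series$nee[nightly] >= band$lwr
  }
  tibble::tibble(
    timestamp = series$timestamp,
    keep = keep,
    reason = ifelse(keep, NA_character_, "ci_underestimate")
  )
}
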