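#' Median diurnal cycle of the flux
#'
#' Per half-hour time-of-day slot, the median of the observed NEE across
#' the days of the series.  Slots never observed are reported with a
#' missing median, not zero.
#'
#' @param series A flux series tibble (`timestamp`, `nee`, `qc`).
#' @param min_days Minimum number of distinct days required (default 7).
#' @return A tibble with 48 rows: `tod` (interval-end hours, 0.5 .. 24),
#'   `median_nee`, `n`.
#' @export
median_diurnal_cycle <- function(series, min_days = 7) {
  n_days <- length(unique(as.Date(series$timestamp - 1)))
  if (n_days < min_days) {
    abort(sprintf("median_diurnal_cycle: %d days of data, need >= %d",
                  n_days, min_days),
          class = "mptflux_insufficient_data")
  }
  obs <- series[series$qc == "observed" & !is.na(series$nee), ]
  slots <- tibble::tibble(tod = seq(0.5, 24, by = 0.5))
  agg <- obs |>
    dplyr::mutate(tod = interval_tod(.data$timestamp)) |>
    dplyr::group_by(.data$tod) |>
    dplyr::summarise(median_nee = median(.data$nee), n = dplyr::n(),
                     .groups = "drop")
  out <- dplyr::left_join(slots, agg, by = "tod")
  out$n[is.na(out$n)] <- 0L
  out
}

#' Locate the evening flux peak near sunset
#'
#' The time-of-day slot with the maximum median NEE within the search
#' window.  On hilly terrain the measured nighttime flux peaks shortly
#' after sunset, before drainage flow develops; this peak anchors the
#' two-time-window split.  Ties go to the earliest slot; a peak on the
#' search-window boundary raises a warning (the window may be clipping the
#' true peak).
#'
#' @param cycle A [median_diurnal_cycle()] tibble.
#' @param search_window Two clock hours (default `c(15, 22)`).
#' @return The peak time of day in hours.
#' @export
find_sunset_peak <- function(cycle, search_window = c(15, 22)) {
  inw <- cycle[cycle$tod >= search_window[1] & cycle$tod <= search_window[2] &
                 !is.na(cycle$median_nee), ]
  if (nrow(inw) < 3) {
    abort("find_sunset_peak: fewer than 3 observed slots in the search window",
          class = "mptflux_insufficient_data")
  }
  t_peak <- inw$tod[which.max(inw$median_nee)]
  if (t_peak %in% search_window) {
    warn(sprintf("find_sunset_peak: peak at search-window boundary (%g h)",
                 t_peak))
  }
  t_peak
}

#' Two-time-window split around the evening peak
#'
#' Window 1 spans from `pre_offset` hours before the peak to `post_offset`
#' hours after it (drainage not yet manifested); window 2 is the rest of
#' the night, immediately after window 1 through the last nighttime slot
#' before morning.  Windows wrap across midnight.
#'
#' @param t_peak Peak time of day in hours (from [find_sunset_peak()]).
#' @param pre_offset,post_offset Window-1 extent before/after the peak in
#'   hours (defaults 1 and 2: drainage develops after the peak, so the
#'   window extends further after than before).
#' @param morning_end Clock hour bounding the night on the morning side
#'   (default 12).
#' @return A list of class `window_split` with `t_peak`, `w1_start`,
#'   `w1_end`, `morning_end`.
#' @export
split_windows <- function(t_peak, pre_offset = 1, post_offset = 2,
                          morning_end = 12) {
  structure(list(t_peak = t_peak,
                 w1_start = (t_peak - pre_offset) %% 24,
                 w1_end = (t_peak + post_offset) %% 24,
                 morning_end = morning_end),
            class = "window_split")
}

circ_delta <- function(tod, from) (tod - from) %% 24

#' Assign nighttime records to the two time windows
#'
#' Adds an integer `window` column: 1 for nighttime records inside window
#' 1, 2 for nighttime records after window 1 up to `morning_end`, and 1
#' for any remaining (pre-peak) nighttime records, where drainage has not
#' yet developed.  Daytime records get `NA`.
#'
#' @param series A flux series with `is_night`.
#' @param split A [split_windows()] object.
#' @return `series` with a `window` column.
#' @export
assign_windows <- function(series, split) {
  tod <- interval_tod(series$timestamp)
  w1_len <- circ_delta(split$w1_end, split$w1_start)
  in_w1 <- circ_delta(tod, split$w1_start) <= w1_len
  d2 <- circ_delta(tod, split$w1_end)
  in_w2 <- d2 > 0 & d2 <= circ_delta(split$morning_end, split$w1_end) & !in_w1
  series$window <- dplyr::case_when(
    !series$is_night ~ NA_integer_,
    in_w1 ~ 1L,
    in_w2 ~ 2L,
    TRUE ~ 1L
  )
  series
}

#' Significance of midnight CO2 drainage
#'
#' Welch comparison of the mean normalized nighttime fluxes of the two
#' time windows, both normalized by the SAME temperature response (one
#' fit shared by both windows, so the common temperature signal cancels).
#' Drainage is
#' declared significant only when the window-2 mean is significantly BELOW
#' the window-1 mean: the phenomenon is underestimation by downslope
#' drainage, so a higher window-2 mean is not drainage.  With fewer than
#' `min_n` retained records in either window the outcome is undetermined
#' and treated as negligible, with a warning.
#'
#' @param norm_w1,norm_w2 u*-filtered normalized fluxes of windows 1 and 2.
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum retained records per window (default 10).
#' @return A list with `significant`, `p`, `mean_w1`, `mean_w2`,
#'   `undetermined`.
#' @export
drainage_test <- function(norm_w1, norm_w2, alpha = 0.05, min_n = 10) {
  norm_w1 <- norm_w1[!is.na(norm_w1)]
  norm_w2 <- norm_w2[!is.na(norm_w2)]
  if (length(norm_w1) < min_n || length(norm_w2) < min_n) {
    warn("drainage_test: too few retained records; outcome undetermined, treated as negligible")
    return(list(significant = FALSE, p = NA_real_,
                mean_w1 = if (length(norm_w1)) mean(norm_w1) else NA_real_,
                mean_w2 = if (length(norm_w2)) mean(norm_w2) else NA_real_,
                undetermined = TRUE))
  }
  tt <- mean_difference_test(norm_w2, norm_w1, alpha = alpha,
                             alternative = "two.sided")
  list(significant = tt$significant && tt$mean_moving < tt$mean_reference,
       p = tt$p, mean_w1 = tt$mean_reference, mean_w2 = tt$mean_moving,
       undetermined = FALSE)
}

period_of <- function(series) {
  doy <- lubridate::yday(series$timestamp)
  yr <- lubridate::year(series$timestamp)[1]
  periods <- quarter_periods(yr)
  hit <- periods[periods$doy_start <= min(doy) & periods$doy_end >= max(doy), ]
  if (nrow(hit) == 1) {
    list(label = hit$label, doy_start = hit$doy_start, doy_end = hit$doy_end)
  } else {
    list(label = paste0(min(doy), "-", max(doy)),
         doy_start = min(doy), doy_end = max(doy))
  }
}

#' Modified moving point test for one period
#'
#' The full per-period procedure for hilly-terrain sites: (1) locate the
#' evening flux peak on the median diurnal cycle and split the night into
#' two time windows; (2) run the moving point test independently in each
#' window; (3) test the significance of midnight drainage by comparing the
#' windows' u*-filtered fluxes, normalized by one temperature response
#' fitted to the pooled retained records of both windows; (4) build the
#' filter mask: if drainage is significant every
#' nighttime window-2 record is rejected (reason
#' `"second_window_drainage"`) and window 1 is filtered by its own
#' thresholds; otherwise each window is filtered by its own thresholds
#' (reject u* <= lower threshold as `"low_ustar"`, u* >= an established
#' upper threshold as `"high_ustar"`).  Nighttime records with missing u*
#' are rejected with reason `"missing_ustar"`.
#'
#' If the moving point test fails in a window (insufficient data, fit
#' failure), that window falls back to the baseline fixed threshold
#' `fvf_fallback` and the period is flagged.
#'
#' @param series One period slice of a flux series (with `is_night`; if
#'   absent it is derived from `rg`).
#' @param config An [mpt_config()].
#' @param drainage_alpha Significance level of the drainage test
#'   (default 0.05).
#' @param pre_offset,post_offset Window-1 offsets in hours (defaults 1, 2).
#' @param search_window Peak search window, clock hours (default
#'   `c(15, 22)`).
#' @param fvf_fallback Fixed u* threshold used when the moving point test
#'   fails in a window (default 0.3 m s-1).
#' @return An object of class `mptflux_period_result`: `period`, `t_peak`,
#'   `split`, `mpt_w1`, `mpt_w2`, `drainage`, `mask` (tibble `timestamp`,
#'   `window`, `keep`, `reason`), `flags`.  Supports [tidy()].
#' @export
run_modified_mpt <- function(series, config = mpt_config(),
                             drainage_alpha = 0.05, pre_offset = 1,
                             post_offset = 2, search_window = c(15, 22),
                             fvf_fallback = 0.3) {
  if (!"is_night" %in% names(series)) series <- flag_night(series)
  flags <- character()
  cycle <- median_diurnal_cycle(series)
  t_peak <- find_sunset_peak(cycle, search_window)
  split <- split_windows(t_peak, pre_offset, post_offset)
  series <- assign_windows(series, split)

  night_obs <- function(w) {
    sub <- series[!is.na(series$window) & series$window == w &
                    series$qc == "observed", ]
    sub[, intersect(c("timestamp", "nee", "ta", "ustar"), names(sub))]
  }
  run_window <- function(w) {
    tryCatch(mpt_thresholds(night_obs(w), config),
             mptflux_insufficient_data = function(e) NULL)
  }
  mpt_w1 <- run_window(1)
  mpt_w2 <- run_window(2)
  if (is.null(mpt_w1)) flags <- c(flags, "w1_mpt_failed_fvf_fallback")
  if (is.null(mpt_w2)) flags <- c(flags, "w2_mpt_failed_fvf_fallback")
  thr <- function(m) {
    if (is.null(m)) c(low = fvf_fallback, high = 9999)
    else c(low = m$ustar_low, high = m$ustar_high)
  }
  th1 <- thr(mpt_w1)
  th2 <- thr(mpt_w2)

  # drainage: both windows' u*-retained fluxes normalized by ONE shared
  # temperature response fitted to the pooled retained records of both
  # windows, so the comparison sees the drainage deficit, not a
  # window-specific extrapolation artifact (a 3-h evening window barely
  # constrains the temperature sensitivity)
  retained_records <- function(w, th) {
    sub <- night_obs(w)
    sub[!is.na(sub$ustar) & !is.na(sub$nee) & !is.na(sub$ta) &
          sub$ustar > th["low"] & sub$ustar < th["high"], ]
  }
  pooled <- dplyr::bind_rows(retained_records(1, th1),
                             retained_records(2, th2))
  trf1 <- tryCatch(fit_trf(pooled),
                   mptflux_insufficient_data = function(e) NULL)
  drainage <- if (is.null(trf1) || !isTRUE(trf1$converged)) {
    flags <- c(flags, "drainage_undetermined_no_trf")
    list(significant = FALSE, p = NA_real_, mean_w1 = NA_real_,
         mean_w2 = NA_real_, undetermined = TRUE)
  } else {
    retained_norm <- function(w, th) {
      sub <- retained_records(w, th)
      sub$nee / predict(trf1, sub$ta)
    }
    drainage_test(retained_norm(1, th1), retained_norm(2, th2),
                  alpha = drainage_alpha)
  }

  keep <- rep(TRUE, nrow(series))
  reason <- rep(NA_character_, nrow(series))
  nightly <- series$is_night & series$qc == "observed"
  for (w in 1:2) {
    th <- if (w == 1) th1 else th2
    inw <- nightly & !is.na(series$window) & series$window == w
    miss_u <- inw & is.na(series$ustar)
    if (drainage$significant && w == 2) {
      keep[inw] <- FALSE
      reason[inw] <- "second_window_drainage"
      next
    }
    low_rej <- inw & !is.na(series$ustar) & series$ustar <= th["low"]
    high_rej <- inw & !is.na(series$ustar) & th["high"] < 9999 &
      series$ustar >= th["high"]
    keep[low_rej | high_rej | miss_u] <- FALSE
    reason[low_rej] <- "low_ustar"
    reason[high_rej] <- "high_ustar"
    reason[miss_u] <- "missing_ustar"
  }

  structure(
    list(period = period_of(series), t_peak = t_peak, split = split,
         mpt_w1 = mpt_w1, mpt_w2 = mpt_w2, drainage = drainage,
         mask = tibble::tibble(timestamp = series$timestamp,
                               window = series$window,
                               keep = keep, reason = reason),
         flags = flags),
    class = "mptflux_period_result")
}

#' @export
print.mptflux_period_result <- function(x, ...) {
  cat(sprintf("Modified moving point test, DOY %s\n", x$period$label))
  cat(sprintf("  evening peak at %.1f h; window 1 = [%.1f, %.1f] h\n",
              x$t_peak, x$split$w1_start, x$split$w1_end))
  fmt <- function(m, lab) {
    if (is.null(m)) {
      cat(sprintf("  %s: moving point test failed (fixed-threshold fallback)\n",
                  lab))
    } else {
      hi <- if (m$ustar_high >= 9999) "9999" else sprintf("%.3f", m$ustar_high)
      cat(sprintf("  %s: u*L = %.3f, u*H = %s\n", lab, m$ustar_low, hi))
    }
  }
  fmt(x$mpt_w1, "window 1")
  fmt(x$mpt_w2, "window 2")
  cat(sprintf("  drainage at midnight: %s (p = %.3g)\n",
              if (isTRUE(x$drainage$significant)) "significant" else "negligible",
              x$drainage$p))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname run_modified_mpt
#' @param x An `mptflux_period_result`.
#' @param ... Unused.
#' @export
tidy.mptflux_period_result <- function(x, ...) {
  period_report(list(x))
}
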