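#' Replace rejected and missing nighttime fluxes with modelled respiration
#'
#' Nighttime records that are missing or rejected by a filter mask get
#' `nee_filled` from the temperature response (daily moving-window
#' `r_ref`, site-year `e0`) at the record's air temperature; retained
#' records keep their observations.  Missing air temperature is
#' interpolated linearly across gaps of up to `max_ta_gap` hours; records
#' that still cannot be filled remain missing and are counted in the
#' `unfilled` attribute (with a warning), never silently dropped.
#' Daytime records are passed through unchanged (daytime gaps are not this
#' filter's business).
#'
#' @param series A flux series with `is_night`.
#' @param e0 Site-year temperature sensitivity, deg C.
#' @param rref Daily reference respiration from [estimate_rref()].
#' @param mask Optional filter mask (`timestamp`, `keep`, ...) from
#'   [run_modified_mpt()], [fvf_filter()] or
#'   [ci_underestimation_filter()]; without a mask only missing records
#'   are filled.
#' @return `series` with `nee_filled` and `qc` updated to `"filled"` where
#'   a model value replaced the observation; attribute `unfilled` counts
#'   nighttime records left unresolved.
#' @export
gapfill_nighttime <- function(series, e0, rref, mask = NULL) {
  if (!"is_night" %in% names(series)) series <- flag_night(series)
  keep <- rep(TRUE, nrow(series))
  if (!is.null(mask)) {
    m <- dplyr::left_join(series["timestamp"], mask, by = "timestamp")
    keep <- !isFALSE_vec(m$keep)
  }
  ta <- series$ta
  if (anyNA(ta)) {
    # linear interpolation, accepted only across gaps of <= 6 records (3 h)
    ta_i <- zoo::na.approx(ta, x = as.numeric(series$timestamp), na.rm = FALSE)
    ok <- fill_within_gap(ta, max_gap = 6)
    ta <- ifelse(ok, ta_i, NA)
  }
  to_fill <- series$is_night & (series$qc == "missing" | !keep)
  er_fill <- rep(NA_real_, nrow(series))
  can <- to_fill & !is.na(ta)
  er_fill[can] <- lloyd_taylor(ta[can],
                               rref_lookup(rref, as.Date(series$timestamp[can] - 1)),
                               e0)
  series$nee_filled <- ifelse(to_fill, er_fill, series$nee)
  series$qc <- dplyr::case_when(
    to_fill & !is.na(er_fill) ~ "filled",
    to_fill & is.na(er_fill) ~ "missing",
    TRUE ~ series$qc
  )
  unfilled <- sum(to_fill & is.na(er_fill))
  if (unfilled > 0) {
    warn(sprintf("gapfill_nighttime: %d nighttime records left unfilled (missing Ta beyond the interpolation span)",
                 unfilled))
  }
  attr(series, "unfilled") <- unfilled
  series
}

isFALSE_vec <- function(x) !is.na(x) & !x

# TRUE where the original vector is observed, or lies in an NA gap of at
# most max_gap consecutive records
fill_within_gap <- function(x, max_gap) {
  ok <- !is.na(x)
  r <- rle(ok)
  lens <- rep(r$lengths, r$lengths)
  ok | lens <= max_gap
}

#' Extrapolate nighttime respiration to daytime
#'
#' Evaluates the nighttime-calibrated temperature response at every
#' record's air temperature, giving the modelled ecosystem respiration
#' used for daytime ER (the daytime flux itself mixes respiration and
#' uptake, so ER must come from the nighttime relationship).
#'
#' @inheritParams gapfill_nighttime
#' @return `series` with an `er_model` column (mg CO2 m-2 s-1).
#' @export
estimate_daytime_er <- function(series, e0, rref) {
  ta <- series$ta
  if (anyNA(ta)) {
    ta_i <- zoo::na.approx(ta, x = as.numeric(series$timestamp),
                           na.rm = FALSE)
    ok <- fill_within_gap(ta, max_gap = 6)
    ta <- ifelse(ok, ta_i, NA)
  }
  er <- rep(NA_real_, nrow(series))
  can <- !is.na(ta)
  er[can] <- lloyd_taylor(ta[can],
                          rref_lookup(rref, as.Date(series$timestamp[can] - 1)),
                          e0)
  series$er_model <- er
  series
}

#' Partition net exchange into respiration and gross uptake
#'
#' Builds the per-record ecosystem respiration and gross primary
#' productivity: at night ER is the resolved flux itself (`nee_filled`,
#' observed or filled) and GPP is 0 by convention — residual night noise
#' stays in NEE rather than leaking into GPP; by day ER is the
#' extrapolated model value and GPP = ER - NEE.  The identity
#' `gpp = er - nee_filled` holds at every resolved record.
#'
#' @param series A flux series carrying `nee_filled` (from
#'   [gapfill_nighttime()]) and `er_model` (from [estimate_daytime_er()]).
#' @return `series` with `er` and `gpp` columns.
#' @export
partition_nee <- function(series) {
  stopifnot(all(c("nee_filled", "er_model", "is_night") %in% names(series)))
  series$er <- ifelse(series$is_night, series$nee_filled, series$er_model)
  series$gpp <- series$er - series$nee_filled
  series
}

#' Annual carbon budget
#'
#' Sums the partitioned half-hourly fluxes over the series into annual
#' totals, converting mg CO2 m-2 s-1 over 1800-s intervals to
#' g C m-2 yr-1 with the mass ratio 12.011/44.009 g C per g CO2.  Sign
#' convention: negative NEE is net uptake.  NEE = ER - GPP holds exactly
#' because all three budgets are summed along the same path.
#'
#' @param series A partitioned series ([partition_nee()]); every record
#'   must be resolved (non-missing `nee_filled`, `er`, `gpp`), otherwise a
#'   hard error lists the unresolved count.
#' @return A one-row tibble: `nee`, `gpp`, `er` (g C m-2 yr-1),
#'   `n_records`, `n_filled_night`, `frac_filled_night`.
#' @export
annual_budget <- function(series) {
  bad <- is.na(series$nee_filled) | is.na(series$er) | is.na(series$gpp)
  if (any(bad)) {
    abort(sprintf("annual_budget: %d unresolved records (first at %s)",
                  sum(bad), format(series$timestamp[which(bad)[1]])),
          class = "mptflux_data_error")
  }
  to_gc <- 1800 * C_PER_CO2 / 1000
  night <- series$is_night
  tibble::tibble(
    nee = sum(series$nee_filled) * to_gc,
    gpp = sum(series$gpp) * to_gc,
    er = sum(series$er) * to_gc,
    n_records = nrow(series),
    n_filled_night = sum(night & series$qc == "filled"),
    frac_filled_night = if (any(night)) {
      sum(night & series$qc == "filled") / sum(night)
    } else 0
  )
}
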