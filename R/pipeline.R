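#' Per-period thresholds for a whole series
#'
#' Runs the modified moving point test on every three-month period of the
#' series and collects the summary report.  A failure in one period is
#' surfaced as a flag on that period; the run continues.
#'
#' @param series A flux series (night flagged, or `rg` present).
#' @param config An [mpt_config()].
#' @param ... Passed on to [run_modified_mpt()].
#' @return A list with `results` (named list of period results; failed
#'   periods hold the condition object) and `report` (tibble, one row per
#'   successful period).
#' @export
run_thresholds <- function(series, config = mpt_config(), ...) {
  if (!"is_night" %in% names(series)) series <- flag_night(series)
  slices <- split_periods(series)
  results <- purrr::map(slices, function(sl) {
    tryCatch(run_modified_mpt(sl, config = config, ...),
             error = function(e) e)
  })
  ok <- purrr::map_lgl(results, inherits, "mptflux_period_result")
  if (any(!ok)) {
    warn(sprintf("run_thresholds: %d period(s) failed: %s", sum(!ok),
                 paste(names(results)[!ok], collapse = ", ")))
  }
  report <- if (any(ok)) period_report(results[ok]) else tibble::tibble()
  list(results = results, report = report)
}

#' Nighttime correction, gap-filling, partitioning and budget
#'
#' The end-to-end correction pipeline for one method:
#' \describe{
#'   \item{mpt}{modified moving point test per period; retained nighttime
#'     fluxes are the respiration observations.}
#'   \item{fvf}{fixed friction-velocity threshold (default 0.3 m s-1).}
#'   \item{lrc}{daily light-response intercepts are the respiration
#'     observations; nighttime fluxes below the fitted response's 95%
#'     band are filtered.}
#'   \item{vgf}{daily sunset-peak medians are the respiration
#'     observations; same 95%-band nighttime filter.}
#' }
#' In every case the temperature sensitivity `e0` is then estimated for
#' the site-year ([estimate_e0()]), the reference respiration by moving
#' window ([estimate_rref()]), rejected/missing nighttime records are
#' filled from the temperature response, daytime respiration is
#' extrapolated, NEE is partitioned and the budget summed.
#'
#' @param series A flux series covering the site-year.
#' @param method One of `"mpt"`, `"fvf"`, `"lrc"`, `"vgf"`.
#' @param config An [mpt_config()] (mpt method).
#' @param fvf_threshold Fixed threshold for the fvf method (default 0.3).
#' @param ci_level Band level of the underestimation filter for lrc/vgf
#'   (default 0.95).
#' @param ... Passed on to [run_modified_mpt()] (mpt method).
#' @return An object of class `flux_correction`: `method`, `series`
#'   (partitioned, with `nee_filled`, `er`, `gpp`, `qc`), `budget`,
#'   `mask`, `e0`, `rref`, and for the mpt method `thresholds` (the
#'   [run_thresholds()] output).  Supports [glance()].
#' @export
run_correction <- function(series, method = c("mpt", "fvf", "lrc", "vgf"),
                           config = mpt_config(), fvf_threshold = 0.3,
                           ci_level = 0.95, ...) {
  method <- match.arg(method)
  if (!"is_night" %in% names(series)) series <- flag_night(series)
  thresholds <- NULL

  if (method %in% c("mpt", "fvf")) {
    if (method == "mpt") {
      thresholds <- run_thresholds(series, config = config, ...)
      ok <- purrr::keep(thresholds$results, inherits,
                        "mptflux_period_result")
      if (!length(ok)) {
        abort("run_correction: no period produced thresholds",
              class = "mptflux_data_error")
      }
      mask <- dplyr::bind_rows(purrr::map(ok, "mask"))
    } else {
      mask <- fvf_filter(series, threshold = fvf_threshold)
    }
    m <- dplyr::left_join(series["timestamp"], mask, by = "timestamp")
    retained <- series$is_night & series$qc == "observed" &
      !isFALSE_vec(m$keep)
    er_obs <- series[retained, c("timestamp", "ta", "nee")]
  } else {
    er_obs_daily <- if (method == "lrc") {
      d <- lrc_daily(series)
      tibble::tibble(date = d$date, ta = d$ta, nee = d$r_lrcd)
    } else {
      d <- vgf_rmax(series)
      tibble::tibble(date = d$date, ta = d$ta, nee = d$r_max)
    }
    er_obs_daily <- er_obs_daily[!is.na(er_obs_daily$ta) &
                                   !is.na(er_obs_daily$nee), ]
    er_obs <- tibble::tibble(
      timestamp = as.POSIXct(paste(er_obs_daily$date, "12:00:00"),
                             tz = lubridate::tz(series$timestamp)),
      ta = er_obs_daily$ta, nee = er_obs_daily$nee)
    # 95%-band underestimation filter on the nighttime fluxes
    site_fit <- fit_trf(er_obs)
    if (!site_fit$converged) site_fit <- fit_trf(er_obs, fix_e0 = 309)
    mask <- ci_underestimation_filter(series, site_fit, level = ci_level)
  }

  e0_est <- estimate_e0(er_obs)
  rref <- estimate_rref(er_obs, e0_est$e0)
  filled <- gapfill_nighttime(series, e0_est$e0, rref, mask = mask)
  filled <- estimate_daytime_er(filled, e0_est$e0, rref)
  part <- partition_nee(filled)
  budget <- tryCatch(annual_budget(part), mptflux_data_error = function(e) {
    warn(conditionMessage(e))
    NULL
  })
  structure(
    list(method = method, series = part, budget = budget, mask = mask,
         e0 = e0_est, rref = rref, thresholds = thresholds),
    class = "flux_correction")
}

#' @export
print.flux_correction <- function(x, ...) {
  cat(sprintf("Nighttime flux correction (%s)\n", x$method))
  cat(sprintf("  e0 = %.1f degC%s, r_ref median = %.3g mg CO2 m-2 s-1\n",
              x$e0$e0, if (x$e0$fallback) " [fallback]" else "",
              median(x$rref$r_ref)))
  if (!is.null(x$budget)) {
    cat(sprintf("  budget (g C m-2): NEE %.1f, GPP %.1f, ER %.1f (night filled %.0f%%)\n",
                x$budget$nee, x$budget$gpp, x$budget$er,
                100 * x$budget$frac_filled_night))
  }
  invisible(x)
}

#' @rdname run_correction
#' @param x A `flux_correction`.
#' @export
glance.flux_correction <- function(x, ...) {
  out <- tibble::tibble(method = x$method, e0 = x$e0$e0,
                        e0_fallback = x$e0$fallback)
  if (!is.null(x$budget)) out <- dplyr::bind_cols(out, x$budget)
  out
}

#' Compare correction methods on one series
#'
#' Runs [run_correction()] for each requested method and stacks the
#' resulting budgets, the desk-scale analogue of a multi-method annual
#' budget comparison.
#'
#' @param series A flux series.
#' @param methods Methods to run (default all four).
#' @param ... Passed on to [run_correction()].
#' @return A tibble with one row per method.
#' @export
compare_methods <- function(series,
                            methods = c("mpt", "fvf", "lrc", "vgf"), ...) {
  purrr::map_dfr(methods, function(m) {
    res <- tryCatch(run_correction(series, method = m, ...),
                    error = function(e) NULL)
    if (is.null(res)) {
      return(tibble::tibble(method = m, e0 = NA_real_,
                            e0_fallback = NA))
    }
    glance(res)
  })
}

#' Serialize a correction's budget and parameters to JSON
#'
#' @param correction A `flux_correction`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_budget_json <- function(correction, path) {
  payload <- list(
    method = correction$method,
    e0_degC = correction$e0$e0,
    e0_fallback = correction$e0$fallback,
    budget_gC_m2 = if (!is.null(correction$budget)) {
      as.list(correction$budget[, c("nee", "gpp", "er")])
    },
    frac_filled_night = correction$budget$frac_filled_night,
    units = list(flux = "mg CO2 m-2 s-1", budget = "g C m-2 yr-1",
                 c_per_co2 = C_PER_CO2)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
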