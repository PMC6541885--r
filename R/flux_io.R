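#' Friction velocity from momentum covariances
#'
#' Computes the friction velocity u* = (u'w'^2 + v'w'^2)^(1/4) from the two
#' kinematic momentum covariances.  The result is invariant to the signs of
#' the covariances and to swapping them, and is always non-negative.
#'
#' @param cov_uw,cov_vw Momentum covariances \eqn{\overline{u'w'}},
#'   \eqn{\overline{v'w'}} in m2 s-2.  Vectors are recycled to a common
#'   length; a missing covariance yields a missing u*.
#' @return Friction velocity in m s-1.
#' @examples
#' ustar_from_covariances(-0.09, 0)        # 0.3
#' ustar_from_covariances(-0.03, 0.04)     # sqrt(0.05)
#' @export
ustar_from_covariances <- function(cov_uw, cov_vw) {
  (cov_uw^2 + cov_vw^2)^0.25
}

#' Time of day of a half-hour interval end
#'
#' Returns the hour-of-day label of the interval end, with midnight mapped to
#' 24 so that labels lie in (0, 24] and the 48 half-hour slots of a day are
#' 0.5, 1, ..., 24.  Timestamps label the END of the 30-min averaging
#' interval, local standard time (no DST).
#'
#' @param timestamp POSIXct vector.
#' @return Numeric hours in (0, 24].
#' @export
interval_tod <- function(timestamp) {
  tod <- lubridate::hour(timestamp) + lubridate::minute(timestamp) / 60
  ifelse(tod == 0, 24, tod)
}

default_column_map <- function() {
  c(timestamp = "timestamp", nee = "nee", ustar = "ustar", ta = "ta",
    rg = "rg", cov_uw = "cov_uw", cov_vw = "cov_vw", storage = "storage")
}

#' Read a half-hourly flux/meteorology CSV
#'
#' Reads one row per half-hour into the canonical series tibble used
#' throughout the package: `timestamp` (POSIXct, labels the interval end),
#' `nee` (mg CO2 m-2 s-1, eddy + storage), `ustar` (m s-1), `ta` (deg C),
#' `rg` (W m-2) and `qc` ("observed"/"missing", tracking `nee`).  The
#' missing-value sentinel (and empty cells) become `NA`; gaps in the 30-min
#' grid are inserted as rows with `qc = "missing"` so that a series is never
#' missing rows, only values.
#'
#' If the u* column is absent but both momentum covariances are mapped,
#' u* is computed with [ustar_from_covariances()].  If a storage-flux column
#' is mapped it is summed into `nee` (for files that store the eddy and
#' storage terms separately).
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping canonical names
#'   (`timestamp`, `nee`, `ustar`, `ta`, `rg`, `cov_uw`, `cov_vw`,
#'   `storage`) to file column names.  Defaults to identical names;
#'   only entries present in the file are used.
#' @param missing_sentinel Numeric sentinel encoding missing values on disk
#'   (default -9999).
#' @param tz Time zone of the timestamps (default "UTC", standing in for
#'   local standard time).
#' @return A tibble with columns `timestamp`, `nee`, `ustar`, `ta`, `rg`,
#'   `qc`, ordered and strictly regular on the 30-min grid.
#' @export
read_halfhourly_csv <- function(path, column_map = NULL,
                                missing_sentinel = -9999, tz = "UTC") {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mptflux_io_error")
  }
  map <- default_column_map()
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    map[names(column_map)] <- column_map
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!map[["timestamp"]] %in% names(raw)) {
    abort(paste0("timestamp column '", map[["timestamp"]], "' not found"),
          class = "mptflux_io_error")
  }
  ts_raw <- raw[[map[["timestamp"]]]]
  ts <- if (inherits(ts_raw, "POSIXct")) {
    lubridate::force_tz(ts_raw, tz)
  } else {
    chr <- as.character(ts_raw)
    parsed <- rep(as.POSIXct(NA), length(chr))
    for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                  "%Y/%m/%d %H:%M", "%Y-%m-%dT%H:%M:%OS")) {
      miss <- is.na(parsed)
      if (!any(miss)) break
      parsed[miss] <- as.POSIXct(strptime(chr[miss], fmt, tz = tz))
    }
    parsed
  }
  if (anyNA(ts)) {
    abort(sprintf("unparseable timestamp at row %d of %s",
                  which(is.na(ts))[1], path),
          class = "mptflux_io_error")
  }
  if (any(diff(as.numeric(ts)) <= 0)) {
    abort(sprintf("timestamps not strictly increasing at row %d of %s",
                  which(diff(as.numeric(ts)) <= 0)[1] + 1, path),
          class = "mptflux_io_error")
  }

  get_num <- function(canon) {
    col <- map[[canon]]
    if (is.na(col) || !col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    x <- as.numeric(raw[[col]])
    x[!is.na(x) & x == missing_sentinel] <- NA_real_
    x
  }
  series <- tibble::tibble(
    timestamp = ts,
    nee = get_num("nee"),
    ustar = get_num("ustar"),
    ta = get_num("ta"),
    rg = get_num("rg")
  )
  storage <- get_num("storage")
  if (any(!is.na(storage))) series$nee <- series$nee + storage
  if (all(is.na(series$ustar))) {
    cov_uw <- get_num("cov_uw")
    cov_vw <- get_num("cov_vw")
    if (any(!is.na(cov_uw)) || any(!is.na(cov_vw))) {
      series$ustar <- ustar_from_covariances(cov_uw, cov_vw)
    }
  }
  # insert grid gaps as missing rows
  grid <- seq(min(ts), max(ts), by = 1800)
  series <- dplyr::left_join(tibble::tibble(timestamp = grid), series,
                             by = "timestamp")
  series$qc <- ifelse(is.na(series$nee), "missing", "observed")
  series
}

#' Write a flux series to CSV with a missing-value sentinel
#'
#' Inverse of [read_halfhourly_csv()]: writes the canonical columns with
#' `NA` encoded as the sentinel, in a fixed float format so that
#' read -> write -> read round-trips a series exactly.
#'
#' @param series A flux series tibble.
#' @param path Output path.
#' @param missing_sentinel Sentinel for missing values (default -9999).
#' @return `series`, invisibly.
#' @export
write_halfhourly_csv <- function(series, path, missing_sentinel = -9999) {
  out <- series
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M")
  num <- vapply(out, is.numeric, logical(1))
  # fixed 6-decimal float format: write -> read -> write is bit-stable
  out[num] <- lapply(out[num], function(x) {
    x <- ifelse(is.na(x), missing_sentinel, x)
    sub("\\.?0+$", "", sprintf("%.6f", x))
  })
  readr::write_csv(out, path, progress = FALSE)
  invisible(series)
}

#' Flag nighttime records by incoming shortwave radiation
#'
#' A record is night when `rg < rg_threshold` (strict: `rg` equal to the
#' threshold is day).  Records with missing `rg` inherit the flag of the
#' nearest same-time-of-day record with an observed `rg`.
#'
#' @param series A flux series tibble with an `rg` column.
#' @param rg_threshold Radiation cutoff in W m-2 (default 10), the
#'   flux-community convention for "night" when no solar geometry is
#'   available.
#' @return `series` with a logical `is_night` column.
#' @export
flag_night <- function(series, rg_threshold = 10) {
  if (all(is.na(series$rg))) {
    abort("cannot flag night: all rg values are missing",
          class = "mptflux_data_error")
  }
  night <- series$rg < rg_threshold
  if (anyNA(night)) {
    tod <- interval_tod(series$timestamp)
    idx_na <- which(is.na(night))
    for (i in idx_na) {
      same <- which(tod == tod[i] & !is.na(night))
      if (length(same)) night[i] <- night[same[which.min(abs(same - i))]]
    }
  }
  series$is_night <- night
  series
}

#' Three-month periods of a year
#'
#' The four fixed quarters used for per-period threshold detection:
#' day-of-year 1-90, 91-181, 182-273 and 274-365 (366 in leap years).
#'
#' @param year Calendar year (determines the leap-year end).
#' @return A tibble with `label`, `doy_start`, `doy_end`.
#' @export
quarter_periods <- function(year) {
  last <- if (lubridate::leap_year(year)) 366L else 365L
  tibble::tibble(
    label = c("1-90", "91-181", "182-273", paste0("274-", last)),
    doy_start = c(1L, 91L, 182L, 274L),
    doy_end = c(90L, 181L, 273L, last)
  )
}

#' Split a series into three-month periods
#'
#' Assigns every record to the quarter of its interval-end day of year and
#' splits the series accordingly.  The slices partition the records: the
#' slice lengths always sum to the series length.
#'
#' @param series A flux series tibble.
#' @return A named list of (possibly empty) series slices, one per quarter
#'   present in the series' year(s); names are the period labels.
#' @export
split_periods <- function(series) {
  doy <- lubridate::yday(series$timestamp)
  year <- lubridate::year(series$timestamp)
  out <- list()
  for (yr in sort(unique(year))) {
    periods <- quarter_periods(yr)
    for (k in seq_len(nrow(periods))) {
      sl <- series[year == yr & doy >= periods$doy_start[k] &
                     doy <= periods$doy_end[k], ]
      if (nrow(sl) > 0) {
        nm <- if (length(unique(year)) > 1) {
          paste0(yr, " ", periods$label[k])
        } else {
          periods$label[k]
        }
        out[[nm]] <- sl
      }
    }
  }
  out
}

#' Period report in the two-window summary format
#'
#' Collects per-period modified-MPT results into the standard summary
#' table: lower/upper u* thresholds for the two time windows and the
#' midnight-drainage flag.  An undetermined upper threshold is written with
#' the 9999 sentinel; periods whose thresholds could not be computed get
#' `NA` cells.
#'
#' @param results A list of period results from [run_modified_mpt()], or a
#'   single period result.
#' @param site,year Optional identifiers repeated on every row.
#' @return A tibble with columns `site`, `year`, `doy`, `ustar_low_w1`,
#'   `ustar_high_w1`, `ustar_low_w2`, `ustar_high_w2`, `drainage`.
#' @export
period_report <- function(results, site = NA_character_, year = NA_integer_) {
  if (inherits(results, "mptflux_period_result")) results <- list(results)
  rows <- purrr::map(results, function(res) {
    thr <- function(m, which) {
      if (is.null(m)) return(NA_real_)
      if (which == "low") m$ustar_low else m$ustar_high
    }
    tibble::tibble(
      site = site, year = year, doy = res$period$label,
      ustar_low_w1 = thr(res$mpt_w1, "low"),
      ustar_high_w1 = thr(res$mpt_w1, "high"),
      ustar_low_w2 = thr(res$mpt_w2, "low"),
      ustar_high_w2 = thr(res$mpt_w2, "high"),
      drainage = if (isTRUE(res$drainage$significant)) "significant"
                 else "negligible"
    )
  })
  dplyr::bind_rows(rows)
}

#' Write the period report to CSV
#'
#' @param results As in [period_report()] (or an already-built report
#'   tibble).
#' @param path Output CSV path.
#' @inheritParams period_report
#' @return The report tibble, invisibly.
#' @export
write_period_report <- function(results, path, site = NA_character_,
                                year = NA_integer_) {
  report <- if (is.data.frame(results)) results
            else period_report(results, site = site, year = year)
  out <- report
  for (col in grep("^ustar_", names(out), value = TRUE)) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA, sprintf("%.3f", out[[col]]))
    out[[col]] <- sub("^9999\\.000$", "9999", out[[col]])
  }
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  invisible(report)
}
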