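#' Configuration of the moving point test
#'
#' @param n_moving Points per moving sample (default 25).
#' @param alpha_mpt Per-test significance level of the Welch comparison
#'   (default 0.1).
#' @param run_length Number of consecutive significant moving samples
#'   required to accept a deficit as systematic rather than a noise
#'   excursion (default `2 * n_moving`, i.e. the deficit must persist while
#'   the moving sample turns over completely twice).  See the package
#'   vignette for why a single significant sample is not a usable trigger.
#' @param max_outer_iterations Cap on outer re-normalization rounds
#'   (default 50).
#' @param min_points Minimum usable nighttime records for threshold
#'   detection (default 100).
#' @param direction Alternative of the per-sample Welch test: `"less"`
#'   (default; the moving sample is deficient relative to the reference,
#'   the direction of advection losses) or `"two.sided"`.
#' @return A list of class `mpt_config`.
#' @export
mpt_config <- function(n_moving = 25, alpha_mpt = 0.1,
                       run_length = 2 * n_moving,
                       max_outer_iterations = 50, min_points = 100,
                       direction = c("less", "two.sided")) {
  stopifnot(n_moving >= 5, alpha_mpt > 0, alpha_mpt < 1, run_length >= 1)
  structure(list(n_moving = as.integer(n_moving), alpha_mpt = alpha_mpt,
                 run_length = as.integer(run_length),
                 max_outer_iterations = as.integer(max_outer_iterations),
                 min_points = as.integer(min_points),
                 direction = match.arg(direction)),
            class = "mpt_config")
}

#' Single-pass 3-sigma outlier rule
#'
#' Removes values farther than three sample standard deviations from the
#' mean, in a single pass.  With zero standard deviation everything is
#' retained.
#'
#' @param values Numeric vector (normalized fluxes).
#' @return The retained values.
#' @export
three_sigma_filter <- function(values) {
  values[three_sigma_mask(values)]
}

three_sigma_mask <- function(values) {
  if (length(values) < 2) return(rep(TRUE, length(values)))
  s <- sd(values)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(values)))
  abs(values - mean(values)) <= 3 * s
}

#' Welch comparison of two sample means
#'
#' Two-sample Welch (unequal-variance) t-test of the mean normalized
#' fluxes of a moving sample against a reference sample.  If both samples
#' have zero variance, equal means give p = 1 (not significant) and
#' unequal means p = 0.
#'
#' @param moving,reference Numeric vectors, each of length >= 2.
#' @param alpha Significance level (default 0.1).
#' @param alternative Test direction (default `"two.sided"`; `"less"`
#'   tests whether the moving mean is below the reference mean).
#' @return A list with `significant`, `p`, `mean_moving`, `mean_reference`.
#' @export
mean_difference_test <- function(moving, reference, alpha = 0.1,
                                 alternative = "two.sided") {
  stopifnot(length(moving) >= 2, length(reference) >= 2)
  m_m <- mean(moving)
  m_r <- mean(reference)
  if (sd(moving) == 0 && sd(reference) == 0) {
    p <- if (m_m == m_r) 1 else 0
    if (p == 0 && alternative == "less" && m_m > m_r) p <- 1
  } else {
    p <- stats::t.test(moving, reference, alternative = alternative)$p.value
  }
  list(significant = p < alpha, p = p, mean_moving = m_m,
       mean_reference = m_r)
}

# Rolling Welch p-values of n-point moving samples against the full
# reference, scanning from the highest-u* end downward.  x must be ordered
# by ascending u*.  Returns the vector of p-values, sample 1 = top.
rolling_welch_p <- function(x, n_moving, direction) {
  N <- length(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  m_r <- mean(x)
  v_r <- var(x)
  n_r <- N
  starts <- seq(N - n_moving + 1, 1)
  m <- (cs[starts + n_moving] - cs[starts]) / n_moving
  v <- (cs2[starts + n_moving] - cs2[starts] - n_moving * m^2) / (n_moving - 1)
  v <- pmax(v, 0)
  se2 <- v / n_moving + v_r / n_r
  tt <- (m - m_r) / sqrt(se2)
  df <- se2^2 / ((v / n_moving)^2 / (n_moving - 1) + (v_r / n_r)^2 / (n_r - 1))
  p <- if (direction == "less") pt(tt, df) else 2 * pt(-abs(tt), df)
  degenerate <- !is.finite(tt)
  if (any(degenerate)) {
    p[degenerate] <- ifelse(m[degenerate] == m_r, 1,
                            if (direction == "less") {
                              ifelse(m[degenerate] < m_r, 0, 1)
                            } else 0)
  }
  p
}

first_sustained_run <- function(sig, run_length) {
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= run_length)
  if (!length(ok)) return(NA_integer_)
  ends[ok[1]] - r$lengths[ok[1]] + 1L
}

#' Inner scan of moving samples over the friction-velocity range
#'
#' Slides moving samples of `n_moving` consecutive-u* points from the
#' highest-u* end downward, one point per step, over the (already
#' 3-sigma-retained, threshold-filtered) reference records, and Welch-tests
#' each sample's mean normalized flux against the reference mean.  The scan
#' triggers at the first sustained run of at least `run_length` consecutive
#' significant samples: a run starting at the very first (highest-u*)
#' sample marks an anomalous top stratum and yields an upper-threshold
#' update; a run starting lower marks the onset of a flux deficit and
#' yields a lower-threshold update.  The candidate threshold is the median
#' u* of the run's first moving sample.  If no sustained run exists over
#' the full scan, the outcome is `"none"`.
#'
#' Ties in u* are broken by timestamp order (when a `timestamp` column is
#' present) so the scan is deterministic and invariant to input row order.
#'
#' @param data Data frame with columns `ustar` and `norm` (normalized
#'   flux), optionally `timestamp`; all rows form the reference sample.
#' @param config An [mpt_config()].
#' @return A list with `kind` ("none", "lower" or "upper"), `candidate`
#'   (median u* of the triggering sample, `NA` for "none"), `index` of the
#'   triggering sample (1 = highest-u* sample), and `p`, the vector of
#'   per-sample p-values in scan order.
#' @export
inner_scan <- function(data, config = mpt_config()) {
  ord <- if ("timestamp" %in% names(data)) {
    order(data$ustar, data$timestamp)
  } else {
    order(data$ustar)
  }
  x <- data$norm[ord]
  u <- data$ustar[ord]
  N <- length(x)
  if (N < config$n_moving) {
    abort(sprintf("inner_scan: %d records, need >= n_moving = %d",
                  N, config$n_moving),
          class = "mptflux_insufficient_data")
  }
  p <- rolling_welch_p(x, config$n_moving, config$direction)
  idx <- first_sustained_run(p < config$alpha_mpt, config$run_length)
  if (is.na(idx)) {
    return(list(kind = "none", candidate = NA_real_, index = NA_integer_,
                p = p))
  }
  start <- N - config$n_moving + 1 - (idx - 1)
  cand <- median(u[start:(start + config$n_moving - 1)])
  list(kind = if (idx == 1) "upper" else "lower", candidate = cand,
       index = idx, p = p)
}

#' Friction-velocity thresholds by the moving point test
#'
#' The outer re-normalization loop of the moving point test: starting from
#' the open interval (0, 9999), repeatedly (1) fit the Lloyd-Taylor
#' temperature response to the nighttime records inside the current
#' thresholds, (2) normalize their fluxes by the fitted respiration,
#' (3) remove 3-sigma outliers, (4) sort by u* and run [inner_scan()]; a
#' lower/upper trigger moves the corresponding threshold inward to the
#' candidate and the loop repeats, and a clean scan ends the loop as
#' converged.  Thresholds only ever move inward.  The sentinel 9999 means
#' "no upper threshold found"; a lower threshold of 0 means "none found".
#'
#' If the temperature-response fit fails inside the loop, the last valid
#' thresholds are returned with `converged = FALSE` and diagnostics.
#'
#' @param data Nighttime records: data frame with `nee`, `ta`, `ustar`
#'   (rows with missing values in these are dropped) and optionally
#'   `timestamp`.
#' @param config An [mpt_config()].
#' @return An object of class `mpt_result`: `ustar_low`, `ustar_high`,
#'   `outer_iterations`, `converged`, `n_used` (records inside the final
#'   thresholds), `trf` (the final [fit_trf()] object) and `trace`, a
#'   tibble of threshold updates.  Supports [tidy()].
#' @export
mpt_thresholds <- function(data, config = mpt_config()) {
  keep <- !is.na(data$nee) & !is.na(data$ta) & !is.na(data$ustar)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < config$min_points) {
    abort(sprintf("mpt_thresholds: %d usable records, need >= %d",
                  nrow(data), config$min_points),
          class = "mptflux_insufficient_data")
  }
  low <- 0
  high <- 9999
  converged <- FALSE
  diagnostics <- NULL
  trf <- NULL
  n_used <- NA_integer_
  trace <- list()
  iter <- 0
  while (iter < config$max_outer_iterations) {
    iter <- iter + 1
    inthr <- data$ustar > low & data$ustar < high
    n_used <- sum(inthr)
    if (n_used < config$n_moving) {
      diagnostics <- "too few records inside thresholds to scan"
      break
    }
    sub <- data[inthr, , drop = FALSE]
    trf_iter <- tryCatch(fit_trf(sub), mptflux_insufficient_data = function(e) e)
    if (inherits(trf_iter, "condition") || !trf_iter$converged) {
      trf_iter2 <- tryCatch(fit_trf(sub, fix_e0 = 309),
                            mptflux_insufficient_data = function(e) e)
      if (inherits(trf_iter2, "condition")) {
        diagnostics <- "temperature response fit failed inside the loop"
        break
      }
      trf_iter <- trf_iter2
    }
    trf <- trf_iter
    norm <- sub$nee / predict(trf, sub$ta)
    retained <- three_sigma_mask(norm)
    scan_df <- data.frame(ustar = sub$ustar[retained], norm = norm[retained])
    if ("timestamp" %in% names(sub)) {
      scan_df$timestamp <- sub$timestamp[retained]
    }
    sc <- tryCatch(inner_scan(scan_df, config),
                   mptflux_insufficient_data = function(e) NULL)
    if (is.null(sc)) {
      diagnostics <- "too few retained records to scan"
      break
    }
    if (sc$kind == "none") {
      converged <- TRUE
      break
    }
    trace[[length(trace) + 1]] <- tibble::tibble(
      iteration = iter, kind = sc$kind, candidate = sc$candidate)
    if (sc$kind == "lower") low <- max(low, sc$candidate)
    else high <- min(high, sc$candidate)
  }
  structure(
    list(ustar_low = low, ustar_high = high, outer_iterations = iter,
         converged = converged, n_used = n_used, trf = trf,
         trace = dplyr::bind_rows(trace), diagnostics = diagnostics),
    class = "mpt_result")
}

#' @export
print.mpt_result <- function(x, ...) {
  hi <- if (x$ustar_high >= 9999) "none (9999)" else sprintf("%.3f", x$ustar_high)
  cat("Moving point test u* thresholds\n")
  cat(sprintf("  lower: %.3f m s-1   upper: %s\n", x$ustar_low, hi))
  cat(sprintf("  %d outer iteration(s), converged: %s, n inside = %d\n",
              x$outer_iterations, x$converged, x$n_used))
  if (!is.null(x$diagnostics)) cat("  note:", x$diagnostics, "\n")
  invisible(x)
}

#' @rdname mpt_thresholds
#' @param x An `mpt_result`.
#' @param ... Unused.
#' @export
tidy.mpt_result <- function(x, ...) {
  tibble::tibble(ustar_low = x$ustar_low, ustar_high = x$ustar_high,
                 outer_iterations = x$outer_iterations,
                 converged = x$converged, n_used = x$n_used)
}
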