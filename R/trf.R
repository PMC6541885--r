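#' Lloyd-Taylor temperature response function
#'
#' Ecosystem respiration as a function of air temperature,
#' \deqn{ER = R_{ref} \exp\!\left(E_0 \left[\frac{1}{T_{ref}-T_0} -
#'   \frac{1}{T_a-T_0}\right]\right),}
#' with the conventional constants \eqn{T_{ref} = 10} deg C and
#' \eqn{T_0 = -46.02} deg C.  The function is strictly increasing and
#' continuous in `ta` on \eqn{(T_0, \infty)} and equals `r_ref` at
#' `ta = t_ref` for any parameter values.  `e0` carries units of
#' temperature (deg C), as the closed form requires.
#'
#' @param ta Air temperature, deg C; must exceed `t0`.
#' @param r_ref Reference respiration at `t_ref`, mg CO2 m-2 s-1.
#' @param e0 Temperature-sensitivity parameter, deg C.
#' @param t_ref Reference temperature, deg C (default 10).
#' @param t0 Lower temperature limit, deg C (default -46.02).
#' @return Respiration in mg CO2 m-2 s-1.
#' @examples
#' lloyd_taylor(10, r_ref = 2, e0 = 309)  # exactly 2
#' lloyd_taylor(20, r_ref = 2, e0 = 309)
#' @export
lloyd_taylor <- function(ta, r_ref, e0, t_ref = 10, t0 = -46.02) {
  if (any(!is.na(ta) & ta <= t0)) {
    abort("lloyd_taylor: ta must exceed t0", class = "mptflux_domain_error")
  }
  r_ref * exp(e0 * (1 / (t_ref - t0) - 1 / (ta - t0)))
}

#' Normalize an observed flux by its modelled respiration
#'
#' Divides the measured flux by the temperature-response prediction; a
#' value of 1 means the observation matches the model.
#'
#' @param nee Observed flux, mg CO2 m-2 s-1.
#' @param er_pred Predicted respiration at the same records; must be
#'   strictly positive.
#' @return Dimensionless normalized flux.
#' @export
normalize_flux <- function(nee, er_pred) {
  if (any(!is.na(er_pred) & er_pred <= 0)) {
    abort("normalize_flux: er_pred must be positive",
          class = "mptflux_domain_error")
  }
  nee / er_pred
}

trf_insufficient <- function(msg) {
  abort(msg, class = "mptflux_insufficient_data")
}

new_trf_fit <- function(r_ref, e0, r_ref_se, e0_se, vcov, n_fit, sigma,
                        converged, fixed_e0, t_ref = 10, t0 = -46.02,
                        diagnostics = NULL) {
  structure(
    list(r_ref = r_ref, e0 = e0, r_ref_se = r_ref_se, e0_se = e0_se,
         vcov = vcov, n_fit = n_fit, df_residual = n_fit - if (fixed_e0) 1 else 2,
         sigma = sigma, converged = converged, fixed_e0 = fixed_e0,
         t_ref = t_ref, t0 = t0, diagnostics = diagnostics),
    class = "trf_fit"
  )
}

#' Fit the Lloyd-Taylor temperature response function
#'
#' Nonlinear least squares of [lloyd_taylor()] on observed (temperature,
#' respiration) pairs, the respiration observations being retained
#' (filtered) nighttime fluxes with efflux positive.  With `fix_e0` given,
#' only `r_ref` is free and the fit reduces to a closed-form linear least
#' squares; otherwise both parameters are estimated with a
#' Levenberg-Marquardt trust-region solver (start `r_ref` = mean flux,
#' `e0` = 309; bounds `r_ref` in (0, 100], `e0` in [10, 600]).
#'
#' Non-convergence is reported through the `converged` flag (with solver
#' diagnostics attached), never as an error; too few points or a degenerate
#' temperature range raise an "insufficient data" condition.
#'
#' @param data Data frame with columns `ta` and `nee` (rows with missing
#'   values are dropped).
#' @param fix_e0 Optional fixed temperature sensitivity, deg C.
#' @param min_n Minimum usable pairs (default 10).
#' @param min_ta_range Minimum temperature range, deg C, required when `e0`
#'   is free (default 2).
#' @param t_ref,t0 Constants of the closed form.
#' @return An object of class `trf_fit` with elements `r_ref`, `e0`,
#'   `r_ref_se`, `e0_se`, `vcov`, `n_fit`, `sigma`, `converged`,
#'   `fixed_e0`.  Supports [tidy()], [glance()], [predict()] and
#'   [autoplot()].
#' @export
fit_trf <- function(data, fix_e0 = NULL, min_n = 10, min_ta_range = 2,
                    t_ref = 10, t0 = -46.02) {
  keep <- !is.na(data$ta) & !is.na(data$nee)
  ta <- data$ta[keep]
  y <- data$nee[keep]
  if (length(y) < min_n) {
    trf_insufficient(sprintf("fit_trf: %d usable pairs, need >= %d",
                             length(y), min_n))
  }
  if (is.null(fix_e0)) {
    if (diff(range(ta)) < min_ta_range) {
      trf_insufficient(sprintf(
        "fit_trf: Ta range %.2f below %.2f needed for a free e0",
        diff(range(ta)), min_ta_range))
    }
    df <- data.frame(ta = ta, y = y)
    start <- list(r_ref = max(mean(y), 1e-3), e0 = 309)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ r_ref * exp(e0 * (1 / (t_ref - t0) - 1 / (ta - t0))),
        data = df, start = start,
        lower = c(r_ref = 1e-9, e0 = 10), upper = c(r_ref = 100, e0 = 600),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(new_trf_fit(NA_real_, NA_real_, NA_real_, NA_real_, NULL,
                         length(y), NA_real_, converged = FALSE,
                         fixed_e0 = FALSE, t_ref = t_ref, t0 = t0,
                         diagnostics = conditionMessage(fit)))
    }
    sm <- summary(fit)
    cf <- coef(fit)
    new_trf_fit(cf[["r_ref"]], cf[["e0"]],
                sm$coefficients["r_ref", "Std. Error"],
                sm$coefficients["e0", "Std. Error"],
                vcov(fit), length(y), sm$sigma,
                converged = TRUE, fixed_e0 = FALSE, t_ref = t_ref, t0 = t0)
  } else {
    g <- exp(fix_e0 * (1 / (t_ref - t0) - 1 / (ta - t0)))
    r_ref <- sum(g * y) / sum(g * g)
    resid <- y - r_ref * g
    dfree <- length(y) - 1
    sigma <- sqrt(sum(resid^2) / dfree)
    se <- sigma / sqrt(sum(g * g))
    new_trf_fit(r_ref, fix_e0, se, 0,
                matrix(se^2, 1, 1, dimnames = list("r_ref", "r_ref")),
                length(y), sigma, converged = TRUE, fixed_e0 = TRUE,
                t_ref = t_ref, t0 = t0)
  }
}

#' @export
print.trf_fit <- function(x, ...) {
  cat("Lloyd-Taylor temperature response fit\n")
  cat(sprintf("  r_ref = %.4g (se %.3g) mg CO2 m-2 s-1 at %.0f degC\n",
              x$r_ref, x$r_ref_se, x$t_ref))
  cat(sprintf("  e0    = %.4g (se %.3g) degC%s\n", x$e0, x$e0_se,
              if (x$fixed_e0) " [fixed]" else ""))
  cat(sprintf("  n = %d, sigma = %.3g, converged: %s\n",
              x$n_fit, x$sigma, x$converged))
  invisible(x)
}

#' @export
predict.trf_fit <- function(object, ta, ...) {
  lloyd_taylor(ta, object$r_ref, object$e0, object$t_ref, object$t0)
}

#' @rdname fit_trf
#' @param x A `trf_fit` object.
#' @param ... Unused.
#' @export
tidy.trf_fit <- function(x, ...) {
  tibble::tibble(
    term = c("r_ref", "e0"),
    estimate = c(x$r_ref, x$e0),
    std.error = c(x$r_ref_se, x$e0_se)
  )
}

#' @rdname fit_trf
#' @export
glance.trf_fit <- function(x, ...) {
  tibble::tibble(n = x$n_fit, sigma = x$sigma, converged = x$converged,
                 fixed_e0 = x$fixed_e0, df.residual = x$df_residual)
}

#' Pointwise confidence band of a fitted temperature response
#'
#' First-order (delta-method) error propagation of the fitted parameters
#' through the closed form, with a Student-t quantile at the requested
#' level and the fit's residual degrees of freedom.  With
#' `interval = "prediction"` the residual standard deviation is added in
#' quadrature, giving the band within which a single new observation is
#' expected — the band an observation filter must use.
#'
#' @param fit A `trf_fit` with standard errors.
#' @param ta Temperatures at which to evaluate the band, deg C.
#' @param level Confidence level (default 0.95).
#' @param interval `"confidence"` (default, band of the mean response) or
#'   `"prediction"`.
#' @return A tibble with `ta`, `est`, `lwr`, `upr`.
#' @export
trf_confidence_band <- function(fit, ta, level = 0.95,
                                interval = c("confidence", "prediction")) {
  interval <- match.arg(interval)
  if (is.null(fit$vcov) || anyNA(fit$vcov)) {
    abort("trf_confidence_band: fit carries no standard errors",
          class = "mptflux_domain_error")
  }
  est <- predict(fit, ta)
  h <- 1 / (fit$t_ref - fit$t0) - 1 / (ta - fit$t0)
  g <- exp(fit$e0 * h)
  if (fit$fixed_e0) {
    se <- sqrt(fit$vcov[1, 1]) * g
  } else {
    J <- cbind(g, fit$r_ref * g * h)
    se <- sqrt(rowSums((J %*% fit$vcov) * J))
  }
  if (interval == "prediction") se <- sqrt(se^2 + fit$sigma^2)
  tq <- qt(1 - (1 - level) / 2, fit$df_residual)
  tibble::tibble(ta = ta, est = est, lwr = est - tq * se, upr = est + tq * se)
}

#' Site-year temperature sensitivity by short-term windows
#'
#' Estimates a single `e0` for a site-year from short-term windows, so that
#' seasonally varying drivers not in the temperature response (soil
#' moisture, phenology) do not masquerade as temperature sensitivity:
#' 15-day windows stepped by 5 days are fitted with both parameters free;
#' windows are accepted when they contain at least `min_n` points, span at
#' least 5 deg C of temperature and yield `e0` within [30, 450]; the
#' site-year value is the mean of the three accepted estimates with the
#' smallest relative standard error.  If no window is accepted the
#' conventional default `e0 = 309` is returned with `fallback = TRUE`.
#'
#' @param data Nighttime retained observations: data frame with
#'   `timestamp`, `ta`, `nee`.
#' @param window_days,step_days Window length and step (days).
#' @param min_n Minimum points per window (default 6).
#' @param e0_range Acceptance interval for the fitted `e0` (default
#'   c(30, 450)).
#' @param min_ta_range Minimum within-window temperature span, deg C
#'   (default 5).
#' @return A list with `e0`, `fallback` (logical), and `windows`, a tibble
#'   of all window fits with their acceptance status.
#' @export
estimate_e0 <- function(data, window_days = 15, step_days = 5, min_n = 6,
                        e0_range = c(30, 450), min_ta_range = 5) {
  keep <- !is.na(data$ta) & !is.na(data$nee)
  data <- data[keep, ]
  if (nrow(data) < min_n) {
    warn("estimate_e0: too few observations; falling back to e0 = 309")
    return(list(e0 = 309, fallback = TRUE, windows = tibble::tibble()))
  }
  day <- as.numeric(difftime(data$timestamp, min(data$timestamp),
                             units = "days"))
  starts <- seq(0, max(0, max(day) - window_days), by = step_days)
  if (!length(starts)) starts <- 0
  windows <- purrr::map_dfr(starts, function(s) {
    in_w <- day >= s & day < s + window_days
    sub <- data[in_w, ]
    row <- tibble::tibble(start_day = s, n = nrow(sub),
                          ta_range = if (nrow(sub)) diff(range(sub$ta)) else 0,
                          e0 = NA_real_, e0_se = NA_real_, accepted = FALSE)
    if (row$n < min_n || row$ta_range < min_ta_range) return(row)
    fit <- tryCatch(fit_trf(sub, min_n = min_n, min_ta_range = min_ta_range),
                    mptflux_insufficient_data = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(row)
    row$e0 <- fit$e0
    row$e0_se <- fit$e0_se
    row$accepted <- fit$e0 >= e0_range[1] && fit$e0 <= e0_range[2] &&
      is.finite(fit$e0_se)
    row
  })
  acc <- windows[windows$accepted, ]
  if (!nrow(acc)) {
    warn("estimate_e0: no acceptable short-term window; falling back to e0 = 309")
    return(list(e0 = 309, fallback = TRUE, windows = windows))
  }
  acc <- acc[order(acc$e0_se / acc$e0), ]
  best <- head(acc, 3)
  list(e0 = mean(best$e0), fallback = FALSE, windows = windows)
}

#' Moving-window reference respiration
#'
#' With the site-year `e0` held fixed, fits the single remaining parameter
#' `r_ref` in a moving window (default 30 days, stepped 5 days) over
#' retained nighttime observations, absorbing the slow variation of
#' respiration with soil moisture and phenology.  Daily values are linear
#' interpolations between window centers; windows with fewer than `min_n`
#' points inherit the nearest valid window's value.
#'
#' @inheritParams estimate_e0
#' @param e0 Fixed temperature sensitivity, deg C.
#' @param window_days,step_days Window length and step (days).
#' @param min_n Minimum points per window (default 6).
#' @return A tibble with one row per calendar day spanned by `data`:
#'   `date`, `r_ref`, `n_fit`.
#' @export
estimate_rref <- function(data, e0, window_days = 30, step_days = 5,
                          min_n = 6) {
  keep <- !is.na(data$ta) & !is.na(data$nee)
  data <- data[keep, ]
  if (!nrow(data)) {
    abort("estimate_rref: no usable observations",
          class = "mptflux_insufficient_data")
  }
  date0 <- as.Date(min(data$timestamp) - 1)   # interval-based dating
  date1 <- as.Date(max(data$timestamp) - 1)
  day <- as.numeric(difftime(data$timestamp, as.POSIXct(paste(date0, "00:00:00"),
                                                        tz = lubridate::tz(data$timestamp)),
                             units = "days"))
  span <- as.numeric(date1 - date0) + 1
  centers <- seq(window_days / 2, max(window_days / 2, span - window_days / 2),
                 by = step_days)
  fits <- purrr::map_dfr(centers, function(ctr) {
    in_w <- day >= ctr - window_days / 2 & day < ctr + window_days / 2
    sub <- data[in_w, ]
    r <- NA_real_
    if (nrow(sub) >= min_n) {
      fit <- tryCatch(fit_trf(sub, fix_e0 = e0, min_n = min_n),
                      mptflux_insufficient_data = function(e) NULL)
      if (!is.null(fit) && fit$converged) r <- fit$r_ref
    }
    tibble::tibble(center = ctr, r_ref = r, n_fit = nrow(sub))
  })
  if (all(is.na(fits$r_ref))) {
    abort("estimate_rref: no window with enough data",
          class = "mptflux_insufficient_data")
  }
  # invalid windows inherit the nearest valid window's value
  valid <- which(!is.na(fits$r_ref))
  for (i in which(is.na(fits$r_ref))) {
    fits$r_ref[i] <- fits$r_ref[valid[which.min(abs(valid - i))]]
  }
  days_out <- seq(0.5, span - 0.5, by = 1)
  if (nrow(fits) == 1) {
    r_daily <- rep(fits$r_ref, length(days_out))
    n_daily <- rep(fits$n_fit, length(days_out))
  } else {
    r_daily <- approx(fits$center, fits$r_ref, xout = days_out, rule = 2)$y
    n_daily <- approx(fits$center, fits$n_fit, xout = days_out, rule = 2,
                      method = "constant")$y
  }
  tibble::tibble(date = seq(date0, date1, by = 1),
                 r_ref = r_daily, n_fit = as.integer(n_daily))
}

rref_lookup <- function(rref, dates) {
  idx <- match(dates, rref$date)
  out <- rref$r_ref[idx]
  if (anyNA(out)) {
    # clamp to the covered span
    before <- is.na(idx) & dates < min(rref$date)
    after <- is.na(idx) & dates > max(rref$date)
    out[before] <- rref$r_ref[1]
    out[after] <- rref$r_ref[nrow(rref)]
  }
  out
}
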