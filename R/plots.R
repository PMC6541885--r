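#' Binned dependence of the normalized nighttime flux on u*
#'
#' The standard diagnostic: nighttime fluxes are normalized by a
#' temperature response fitted to observations above a fixed u* cutoff,
#' binned by u*, and plotted as bin means with standard-deviation bars —
#' optionally separated by time window to expose drainage (a window-2
#' curve sitting below window 1 even at high u*).
#'
#' @param series A flux series with `is_night` (and optionally a `window`
#'   column from [assign_windows()]).
#' @param trf_ustar_min u* cutoff for the normalizing fit (default 0.3).
#' @param n_bins Number of u* bins (default 20).
#' @param by_window Facet by the `window` column when present.
#' @return A ggplot object.
#' @export
plot_ustar_bins <- function(series, trf_ustar_min = 0.3, n_bins = 20,
                            by_window = TRUE) {
  if (!"is_night" %in% names(series)) series <- flag_night(series)
  night <- series[series$is_night & series$qc == "observed" &
                    !is.na(series$ustar) & !is.na(series$ta) &
                    !is.na(series$nee), ]
  fit <- fit_trf(night[night$ustar > trf_ustar_min, ])
  night$norm <- night$nee / predict(fit, night$ta)
  night$bin <- cut(night$ustar, breaks = n_bins)
  grp <- c("bin", if (by_window && "window" %in% names(night)) "window")
  df <- night |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(ustar = mean(.data$ustar), mean = mean(.data$norm),
                     sd = sd(.data$norm), .groups = "drop")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ustar, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "u* (m s⁻¹)",
                  y = "normalized nighttime CO₂ flux")
  if (by_window && "window" %in% names(night)) {
    p <- p + ggplot2::facet_wrap(~window,
                                 labeller = ggplot2::label_both)
  }
  p
}

#' Plot a median diurnal cycle
#'
#' @param cycle A [median_diurnal_cycle()] tibble.
#' @param search_window Optional peak search window to shade.
#' @return A ggplot object.
#' @export
plot_diurnal_cycle <- function(cycle, search_window = NULL) {
  p <- ggplot2::ggplot(cycle, ggplot2::aes(x = .data$tod,
                                           y = .data$median_nee)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time of day (h, interval end)",
                  y = "median NEE (mg CO₂ m⁻² s⁻¹)")
  if (!is.null(search_window)) {
    p <- p + ggplot2::annotate("rect", xmin = search_window[1],
                               xmax = search_window[2], ymin = -Inf,
                               ymax = Inf, alpha = 0.1)
  }
  p
}

#' @describeIn fit_trf Plot the fitted temperature response with its 95%
#'   band (and the fitted data when supplied).
#' @param object A `trf_fit`.
#' @param data Optional data frame with `ta` and `nee` to overlay.
#' @export
autoplot.trf_fit <- function(object, data = NULL, ...) {
  ta_range <- if (!is.null(data)) range(data$ta, na.rm = TRUE) else c(-5, 30)
  band <- trf_confidence_band(object, seq(ta_range[1], ta_range[2],
                                          length.out = 200))
  p <- ggplot2::ggplot(band, ggplot2::aes(x = .data$ta)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$est)) +
    ggplot2::labs(x = "air temperature (°C)",
                  y = "ER (mg CO₂ m⁻² s⁻¹)")
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = data,
                                 ggplot2::aes(x = .data$ta, y = .data$nee),
                                 size = 0.5, alpha = 0.4)
  }
  p
}
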