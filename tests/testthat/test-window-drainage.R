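test_that("median diurnal cycle is the per-slot median of observed fluxes", {
  # 8 identical days: the cycle equals any one day
  pat <- c(rep(0.3, 12), seq(0.3, -0.5, length.out = 24), rep(0.25, 12))
  s <- make_series(48 * 8, nee = rep(pat, 8))
  cyc <- median_diurnal_cycle(s)
  expect_equal(cyc$median_nee, pat)
  expect_equal(cyc$n, rep(8L, 48))

  # an outlier day does not move the medians (brute-force check)
  s2 <- s
  s2$nee[49:96] <- 50
  cyc2 <- median_diurnal_cycle(s2)
  brute <- vapply(1:48, function(k) {
    median(s2$nee[seq(k, 48 * 8, by = 48)])
  }, numeric(1))
  expect_equal(cyc2$median_nee, brute)
  expect_equal(cyc2$median_nee, pat)

  # a never-observed slot is absent, not zero
  s3 <- s
  s3$nee[seq(5, nrow(s3), by = 48)] <- NA
  s3$qc <- ifelse(is.na(s3$nee), "missing", "observed")
  expect_true(is.na(median_diurnal_cycle(s3)$median_nee[5]))

  expect_error(median_diurnal_cycle(make_series(48 * 6)),
               class = "mptflux_insufficient_data")
})

test_that("sunset-peak search obeys the window, ties and boundary rules", {
  cyc <- tibble::tibble(tod = seq(0.5, 24, 0.5),
                        median_nee = 0.1, n = 10L)
  cyc$median_nee[cyc$tod == 18.5] <- 0.9
  expect_equal(find_sunset_peak(cyc), 18.5)

  # flat cycle: earliest slot in the search window
  flat <- tibble::tibble(tod = seq(0.5, 24, 0.5), median_nee = 0.2, n = 10L)
  expect_warning(tp <- find_sunset_peak(flat), "boundary")
  expect_equal(tp, 15)

  # maximum on the boundary warns
  b <- flat
  b$median_nee[b$tod == 22] <- 1
  expect_warning(expect_equal(find_sunset_peak(b), 22), "boundary")

  none <- flat
  none$median_nee <- NA_real_
  expect_error(find_sunset_peak(none), class = "mptflux_insufficient_data")
})

test_that("window split arithmetic, degenerate offsets and midnight wrap", {
  sp <- split_windows(18)
  expect_equal(sp$w1_start, 17)
  expect_equal(sp$w1_end, 20)

  sp0 <- split_windows(18, post_offset = 0)
  expect_equal(sp0$w1_end, 18)

  # assignment: night 18:00-06:00, peak 18:00
  g <- generate_flux(synth_config(seed = 1, n_days = 10))
  s <- assign_windows(g$series, sp)
  tod <- mptflux::interval_tod(s$timestamp)
  expect_true(all(is.na(s$window[!s$is_night])))
  expect_true(all(s$window[s$is_night & tod >= 18 & tod <= 20] == 1))
  # window 2 wraps across midnight without splitting
  expect_true(all(s$window[s$is_night & (tod >= 20.5 | tod <= 6)] == 2))
})

test_that("drainage significance is one-sided with an undetermined guard", {
  withr::with_seed(6, {
    w1 <- rnorm(100, 1, 0.2)
    w2_same <- rnorm(100, 1, 0.2)
    w2_low <- rnorm(100, 0.3, 0.2)
    w2_high <- rnorm(100, 1.8, 0.2)
  })
  expect_false(drainage_test(w1, w2_same)$significant)

  dt <- drainage_test(w1, w2_low)
  expect_true(dt$significant)
  expect_equal(dt$p, stats::t.test(w2_low, w1)$p.value)

  # a HIGHER window-2 mean is not drainage, however significant the test
  expect_false(drainage_test(w1, w2_high)$significant)

  expect_warning(u <- drainage_test(w1, w2_low[1:5]), "undetermined")
  expect_true(u$undetermined)
  expect_false(u$significant)
})

test_that("modified MPT end-to-end: drainage-free period filters by window thresholds", {
  g <- generate_flux(scenario_library(seed = 21)$threshold_only)
  res <- run_modified_mpt(g$series)
  expect_false(res$drainage$significant)
  expect_equal(res$mpt_w1$ustar_low, 0.25, tolerance = 0.06 / 0.25)
  expect_equal(res$mpt_w2$ustar_low, 0.25, tolerance = 0.06 / 0.25)
  # rejected night records are exactly the below-threshold ones, per window
  m <- res$mask
  night_obs <- g$series$is_night & g$series$qc == "observed"
  for (w in 1:2) {
    th <- if (w == 1) res$mpt_w1$ustar_low else res$mpt_w2$ustar_low
    inw <- night_obs & !is.na(m$window) & m$window == w
    expect_identical(m$keep[inw], g$series$ustar[inw] > th)
  }
  expect_true(all(m$keep[!night_obs]))
})

test_that("modified MPT end-to-end: significant drainage rejects all of window 2", {
  g <- generate_flux(scenario_library(seed = 4)$threshold_plus_drainage)
  res <- run_modified_mpt(g$series)
  expect_true(res$drainage$significant)
  m <- res$mask
  w2_night <- g$series$is_night & g$series$qc == "observed" &
    !is.na(m$window) & m$window == 2
  expect_true(all(!m$keep[w2_night]))
  expect_true(all(m$reason[w2_night] == "second_window_drainage"))

  # the temperature response fitted on window-2 retained data sits below
  # the window-1 fit at every temperature (the drainage fingerprint)
  night <- g$series[g$series$is_night & g$series$qc == "observed", ]
  tod <- mptflux::interval_tod(night$timestamp)
  f1 <- fit_trf(night[!is.na(m$window[match(night$timestamp, m$timestamp)]) &
                        m$window[match(night$timestamp, m$timestamp)] == 1 &
                        night$ustar > res$mpt_w1$ustar_low, ])
  f2 <- fit_trf(night[!is.na(m$window[match(night$timestamp, m$timestamp)]) &
                        m$window[match(night$timestamp, m$timestamp)] == 2 &
                        night$ustar > res$mpt_w2$ustar_low, ])
  ta_grid <- seq(-5, 10, 1)
  expect_true(all(predict(f2, ta_grid) < predict(f1, ta_grid)))
})

test_that("the filter mask is a pure function of its inputs", {
  g <- generate_flux(scenario_library(seed = 13)$threshold_plus_drainage)
  r1 <- run_modified_mpt(g$series)
  r2 <- run_modified_mpt(g$series)
  expect_identical(r1$mask, r2$mask)
  expect_identical(tidy(r1), tidy(r2))
})

test_that("drainage detection rate rises with injected suppression strength", {
  rate <- vapply(c(1, 0.6, 0.2), function(f) {
    hits <- vapply(1:6, function(s) {
      g <- generate_flux(synth_config(seed = s, ustar_threshold = 0.25,
                                      suppression_factor = 0.3,
                                      drainage_enabled = TRUE,
                                      suppression_factor_w2 = f))
      run_modified_mpt(g$series)$drainage$significant
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_equal(rate[3], 1)
})
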