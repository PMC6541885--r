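test_that("Lloyd-Taylor closed form: reference point, hand values, domain", {
  withr::with_seed(1, {
    r <- runif(200, 0.01, 5)
    e <- runif(200, 30, 450)
  })
  expect_equal(lloyd_taylor(10, r, e), r, tolerance = 1e-14)
  expect_equal(lloyd_taylor(20, 2, 309),
               2 * exp(309 * (1 / 56.02 - 1 / 66.02)), tolerance = 1e-12)
  expect_equal(lloyd_taylor(20, 2, 309), 4.612, tolerance = 1e-3)
  expect_equal(lloyd_taylor(0, 2, 309), 0.603, tolerance = 1e-3)
  expect_error(lloyd_taylor(-46.02, 2, 309), class = "mptflux_domain_error")
  # strictly increasing in ta
  ta <- seq(-40, 40, by = 0.5)
  expect_true(all(diff(lloyd_taylor(ta, 1.3, 200)) > 0))
})

test_that("flux normalization is the plain ratio with a positivity guard", {
  expect_equal(normalize_flux(0.3, 0.3), 1)
  expect_equal(normalize_flux(0, 0.3), 0)
  expect_equal(normalize_flux(0.45, 0.3), 1.5)
  expect_error(normalize_flux(0.3, 0), class = "mptflux_domain_error")
  ta <- seq(-5, 25, by = 1)
  expect_equal(normalize_flux(lloyd_taylor(ta, 2, 250),
                              lloyd_taylor(ta, 2, 250)),
               rep(1, length(ta)))
})

trf_data <- function(n, r_ref, e0, noise_sd = 0, seed = 1,
                     ta_range = c(-5, 25)) {
  withr::with_seed(seed, {
    ta <- runif(n, ta_range[1], ta_range[2])
    y <- lloyd_taylor(ta, r_ref, e0) *
      exp(rnorm(n, -noise_sd^2 / 2, noise_sd))
  })
  tibble::tibble(ta = ta, nee = y)
}

test_that("temperature-response fit recovers noiseless truth to 1e-6", {
  d <- trf_data(200, r_ref = 3, e0 = 250)
  f <- fit_trf(d)
  expect_true(f$converged)
  expect_equal(f$r_ref, 3, tolerance = 1e-6)
  expect_equal(f$e0, 250, tolerance = 1e-6)

  f1 <- fit_trf(d, fix_e0 = 250)
  expect_equal(f1$r_ref, 3, tolerance = 1e-10)
  expect_equal(f1$e0_se, 0)

  expect_error(fit_trf(d[1:5, ]), class = "mptflux_insufficient_data")
  expect_error(fit_trf(tibble::tibble(ta = rep(10, 20), nee = 2)),
               class = "mptflux_insufficient_data")
})

test_that("fit is scale-equivariant in the flux", {
  d <- trf_data(150, r_ref = 1.2, e0 = 180)
  f1 <- fit_trf(d)
  d2 <- d
  d2$nee <- d2$nee * 7
  f2 <- fit_trf(d2)
  expect_equal(f2$r_ref, 7 * f1$r_ref, tolerance = 1e-6)
  expect_equal(f2$e0, f1$e0, tolerance = 1e-6)
})

test_that("tidy and glance expose the fitted parameters", {
  f <- fit_trf(trf_data(100, 2, 300, noise_sd = 0.1))
  td <- tidy(f)
  expect_equal(td$term, c("r_ref", "e0"))
  expect_true(all(td$std.error > 0))
  expect_true(glance(f)$converged)
})

test_that("site-year e0 is recovered from short-term windows", {
  g <- generate_flux(synth_config(seed = 11, n_days = 365, e0 = 200,
                                  noise_mult_sd = 0.05,
                                  suppression_factor = 1))
  night <- g$series[g$series$is_night, c("timestamp", "ta", "nee")]
  est <- estimate_e0(night)
  expect_false(est$fallback)
  expect_equal(est$e0, 200, tolerance = 20 / 200)
})

test_that("e0 falls back to 309 with a warning when no window is acceptable", {
  # constant temperature: no window can span 5 degC
  d <- tibble::tibble(
    timestamp = as.POSIXct("2009-01-01 00:30", tz = "UTC") + 1800 * 0:999,
    ta = 5, nee = 1)
  expect_warning(est <- estimate_e0(d), "falling back")
  expect_true(est$fallback)
  expect_equal(est$e0, 309)
})

test_that("moving-window r_ref tracks stationary and shifting truth", {
  ts <- as.POSIXct("2009-01-01 00:30", tz = "UTC") + 1800 * 0:(48 * 120 - 1)
  withr::with_seed(4, ta <- runif(length(ts), 0, 20))
  d <- tibble::tibble(timestamp = ts, ta = ta,
                      nee = lloyd_taylor(ta, 3, 250))
  rr <- estimate_rref(d, e0 = 250)
  expect_equal(nrow(rr), 120)
  expect_equal(rr$r_ref, rep(3, 120), tolerance = 1e-8)

  # step change: r_ref 2 -> 4 at day 60; transition monotone, <= 30 days
  d2 <- d
  day <- as.numeric(as.Date(d2$timestamp - 1) - as.Date("2009-01-01"))
  d2$nee <- lloyd_taylor(ta, ifelse(day < 60, 2, 4), 250)
  rr2 <- estimate_rref(d2, e0 = 250)
  expect_true(all(diff(rr2$r_ref) >= -1e-9))
  expect_lt(sum(rr2$r_ref > 2.05 & rr2$r_ref < 3.95), 31)

  # single valid window: constant series
  rr3 <- estimate_rref(d[1:(48 * 30), ], e0 = 250)
  expect_equal(unique(round(rr3$r_ref, 8)), 3)
})

test_that("confidence band collapses with zero error, nests across levels, and covers", {
  f <- fit_trf(trf_data(200, 2, 250))  # noiseless: near-zero SEs
  b <- trf_confidence_band(f, seq(0, 20, 5))
  expect_equal(b$lwr, b$est, tolerance = 1e-6)
  expect_equal(b$upr, b$est, tolerance = 1e-6)

  fn <- fit_trf(trf_data(200, 2, 250, noise_sd = 0.2))
  b95 <- trf_confidence_band(fn, 0:20, level = 0.95)
  b99 <- trf_confidence_band(fn, 0:20, level = 0.99)
  expect_true(all(b99$lwr < b95$lwr) && all(b99$upr > b95$upr))

  fe <- fn
  fe$vcov <- NULL
  expect_error(trf_confidence_band(fe, 10), class = "mptflux_domain_error")

  # delta-method coverage of the true mean response at one temperature
  hits <- vapply(1:120, function(s) {
    f <- fit_trf(trf_data(1000, 2, 250, noise_sd = 0.2, seed = s))
    b <- trf_confidence_band(f, 15)
    b$lwr <= lloyd_taylor(15, 2, 250) && lloyd_taylor(15, 2, 250) <= b$upr
  }, logical(1))
  expect_gt(mean(hits), 0.89)
  expect_lt(mean(hits), 0.995)
})
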