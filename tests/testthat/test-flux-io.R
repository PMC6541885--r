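test_that("friction velocity from covariances matches the closed form", {
  expect_identical(ustar_from_covariances(0, 0), 0)
  expect_equal(ustar_from_covariances(-0.09, 0), 0.3, tolerance = 1e-12)
  expect_equal(ustar_from_covariances(-0.03, 0.04), sqrt(0.05),
               tolerance = 1e-12)
  # sign and swap invariance, missingness propagation
  withr::with_seed(1, {
    a <- rnorm(50, 0, 0.1)
    b <- rnorm(50, 0, 0.1)
  })
  expect_equal(ustar_from_covariances(a, b), ustar_from_covariances(-a, -b))
  expect_equal(ustar_from_covariances(a, b), ustar_from_covariances(b, a))
  expect_true(all(ustar_from_covariances(a, b) >= 0))
  expect_true(is.na(ustar_from_covariances(NA, 0.1)))
})

write_toy_csv <- function(df, path = withr::local_tempfile(fileext = ".csv",
                                                           .local_envir = parent.frame())) {
  readr::write_csv(df, path)
  path
}

test_that("reader maps the missing sentinel and inserts grid gaps", {
  ts <- format(as.POSIXct("2009-06-01 00:30", tz = "UTC") + 1800 * 0:2,
               "%Y-%m-%d %H:%M")
  p <- write_toy_csv(data.frame(timestamp = ts, nee = c(0.1, -9999, 0.3),
                                ustar = 0.4, ta = 15, rg = 0))
  s <- read_halfhourly_csv(p)
  expect_equal(nrow(s), 3)
  expect_equal(sum(s$qc == "missing"), 1)
  expect_true(is.na(s$nee[2]))

  # a 1-hour gap: two absent rows appear as missing records
  p2 <- write_toy_csv(data.frame(
    timestamp = ts[c(1, 3)][c(1, 2)], nee = c(0.1, 0.3), ustar = 0.4,
    ta = 15, rg = 0)[c(1, 2), ])
  s2 <- read_halfhourly_csv(p2)
  expect_equal(nrow(s2), 3)
  expect_equal(s2$qc, c("observed", "missing", "observed"))
})

test_that("reader falls back to covariances for u* and errors on bad input", {
  ts <- format(as.POSIXct("2009-06-01 00:30", tz = "UTC") + 1800 * 0:1,
               "%Y-%m-%d %H:%M")
  p <- write_toy_csv(data.frame(timestamp = ts, nee = 0.1, ta = 15, rg = 0,
                                cov_uw = -0.09, cov_vw = 0))
  s <- read_halfhourly_csv(p)
  expect_equal(s$ustar, c(0.3, 0.3), tolerance = 1e-12)

  p_bad <- write_toy_csv(data.frame(timestamp = c(ts[1], "not a time"),
                                    nee = 0.1, ta = 15, rg = 0))
  expect_error(read_halfhourly_csv(p_bad), class = "mptflux_io_error")
  p_rev <- write_toy_csv(data.frame(timestamp = rev(ts), nee = 0.1,
                                    ta = 15, rg = 0))
  expect_error(read_halfhourly_csv(p_rev), class = "mptflux_io_error")
})

test_that("a mapped storage column is summed into nee", {
  ts <- format(as.POSIXct("2009-06-01 00:30", tz = "UTC") + 1800 * 0:1,
               "%Y-%m-%d %H:%M")
  p <- write_toy_csv(data.frame(timestamp = ts, fc = c(0.1, 0.2),
                                sc = c(0.05, -0.05), ustar = 0.4,
                                ta = 15, rg = 0))
  s <- read_halfhourly_csv(p, column_map = c(nee = "fc", storage = "sc"))
  expect_equal(s$nee, c(0.15, 0.15))
})

test_that("series round-trips through write and read unchanged", {
  g <- generate_flux(synth_config(seed = 3, n_days = 7, missing_frac = 0.05))
  p <- withr::local_tempfile(fileext = ".csv")
  write_halfhourly_csv(g$series[c("timestamp", "nee", "ustar", "ta", "rg", "qc")], p)
  back <- read_halfhourly_csv(p)
  # second pass must be bit-identical
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_halfhourly_csv(back, p2)
  expect_identical(readLines(p), readLines(p2))
  expect_true(max(abs(back$nee - g$series$nee), na.rm = TRUE) < 1e-6)
  expect_equal(back$qc, g$series$qc)
})

test_that("night flag uses a strict radiation cutoff and inherits over gaps", {
  s <- make_series(6, rg = c(0, 500, 10, 9.99, NA, NA))
  f <- flag_night(s)
  expect_equal(f$is_night[1:4], c(TRUE, FALSE, FALSE, TRUE))
  # missing rg inherits the nearest same-time-of-day flag: build 2 days
  s2 <- make_series(96, rg = c(rep(c(0, 500), each = 24),
                               rep(c(0, 500), each = 24)))
  s2$rg[50] <- NA  # day-2 record, same slot as a night record on day 1
  f2 <- flag_night(s2)
  expect_equal(f2$is_night[50], f2$is_night[2])
  expect_error(flag_night(make_series(4, rg = NA)),
               class = "mptflux_data_error")
})

test_that("quarters partition the year by interval-end day of year", {
  expect_equal(quarter_periods(2008)$label[4], "274-366")
  expect_equal(quarter_periods(2009)$doy_end, c(90L, 181L, 273L, 365L))

  g <- generate_flux(synth_config(seed = 1, n_days = 365))
  sl <- split_periods(g$series)
  expect_equal(sum(vapply(sl, nrow, integer(1))), nrow(g$series))
  # midnight stamps belong to the day they land on, so the first quarter
  # is one record short of 90 x 48 and Dec 31 24:00 spills into next year
  expect_equal(unname(vapply(sl, nrow, integer(1))[1:4]),
               c(90L * 48L - 1L, 91L * 48L, 92L * 48L, 92L * 48L))

  one_q <- split_periods(g$series[1:480, ])
  expect_length(one_q, 1)
})

test_that("period report uses the 9999 sentinel and NA for absent results", {
  g <- generate_flux(scenario_library(seed = 2)$threshold_plus_drainage)
  res <- run_modified_mpt(g$series)
  rep <- period_report(list(res), site = "SYN", year = 2009)
  expect_equal(rep$ustar_high_w1, 9999)
  expect_equal(rep$drainage, "significant")

  p <- withr::local_tempfile(fileext = ".csv")
  write_period_report(list(res), p, site = "SYN", year = 2009)
  txt <- readr::read_csv(p, col_types = readr::cols(.default = "c"))
  expect_equal(txt$ustar_high_w1, "9999")

  # degenerate: a failed window writes NA cells
  res$mpt_w2 <- NULL
  rep2 <- period_report(list(res))
  expect_true(is.na(rep2$ustar_low_w2))
})
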