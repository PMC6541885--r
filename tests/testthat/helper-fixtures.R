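# Shared fixture builders.  Everything is generated in code at test time.

# Regular half-hourly series from vectors (timestamps label interval ends).
make_series <- function(n, start = "2009-01-01 00:30", nee = 0.2,
                        ustar = 0.3, ta = 10, rg = 0) {
  ts <- as.POSIXct(start, tz = "UTC") + 1800 * (seq_len(n) - 1)
  tibble::tibble(
    timestamp = ts,
    nee = rep_len(nee, n), ustar = rep_len(ustar, n),
    ta = rep_len(ta, n), rg = rep_len(rg, n),
    qc = ifelse(is.na(rep_len(nee, n)), "missing", "observed")
  )
}

# Nighttime records with a known u*-suppression geometry, for scan tests:
# normalized-flux column included so inner_scan can run directly.
make_scan_fixture <- function(n, threshold = NA, suppression = 1,
                              noise_sd = 0.2, seed = 1,
                              top_deficit_n = 0, top_deficit_factor = 0.3) {
  withr::with_seed(seed, {
    u <- sort(rlnorm(n, log(0.3), 0.5))
    norm <- exp(rnorm(n, -noise_sd^2 / 2, noise_sd))
    if (!is.na(threshold)) norm[u < threshold] <- norm[u < threshold] * suppression
    if (top_deficit_n > 0) {
      idx <- (n - top_deficit_n + 1):n
      norm[idx] <- norm[idx] * top_deficit_factor
    }
    tibble::tibble(ustar = u, norm = norm)
  })
}

# Brute-force oracle for the inner scan: evaluates EVERY moving sample with
# an independent stats::t.test call, then applies the sustained-run trigger
# rule.  Shares no code with inner_scan's rolling computation.
oracle_scan <- function(data, config) {
  ord <- order(data$ustar)
  x <- data$norm[ord]
  u <- data$ustar[ord]
  N <- length(x)
  n <- config$n_moving
  starts <- seq(N - n + 1, 1)
  alt <- if (config$direction == "less") "less" else "two.sided"
  p <- vapply(starts, function(s) {
    stats::t.test(x[s:(s + n - 1)], x, alternative = alt)$p.value
  }, numeric(1))
  sig <- p < config$alpha_mpt
  idx <- NA_integer_
  run <- 0L
  for (i in seq_along(sig)) {
    run <- if (sig[i]) run + 1L else 0L
    if (run == config$run_length) { idx <- i - config$run_length + 1L; break }
  }
  if (is.na(idx)) return(list(kind = "none", candidate = NA_real_,
                              index = NA_integer_, p = p))
  s <- starts[idx]
  list(kind = if (idx == 1) "upper" else "lower",
       candidate = median(u[s:(s + n - 1)]), index = idx, p = p)
}

# Annual-sum conversion used when comparing budgets against generator truth.
truth_budget <- function(truth) {
  to_gc <- 1800 * (12.011 / 44.009) / 1000
  tibble::tibble(
    nee = sum(truth$nee_true) * to_gc,
    gpp = sum(truth$gpp_true) * to_gc,
    er = sum(truth$er_true) * to_gc
  )
}
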