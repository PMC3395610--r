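# Composite-signal generator: OUP statistics, scene synthesis, SAM/RAM
# mimic stimuli.

test_that("OUP has unit variance and exponential autocorrelation", {
  # frozen-noise limit: correlation time far beyond the record
  frozen <- generate_oup(1e6, signal_config(1, 2000, seed = 4))
  expect_lt(var(diff(frozen$samples)), 1e-6)
  expect_lt(diff(range(frozen$samples)), 1e-2)

  # stationary statistics at tau_c = 0.5 s, averaged over seeds
  tau <- 0.5
  devs <- numeric(0); vars <- numeric(0)
  acc <- NULL
  for (s in 1:20) {
    x <- generate_oup(tau, signal_config(300, 2000, seed = s))
    vars <- c(vars, var(x$samples))
    ac <- autocorrelation(x, max_lag = 3 * tau, segment_seconds = 300)
    acc <- if (is.null(acc)) ac$acf else acc + ac$acf
  }
  acc <- acc / 20
  lags <- seq(0, 3 * tau, by = 1 / 2000)
  expect_lt(max(abs(acc - exp(-lags / tau))), 0.05)
  expect_gt(mean(vars), 0.85)
  expect_lt(mean(vars), 1.15)
  # lag-tau_c value close to 1/e
  i <- which.min(abs(lags - tau))
  expect_lt(abs(acc[i] - exp(-1)), 0.05)
})

test_that("OUP generation is deterministic under a fixed seed and rejects bad input", {
  cfg <- signal_config(2, 2000, seed = 9)
  expect_identical(generate_oup(0.5, cfg)$samples,
                   generate_oup(0.5, cfg)$samples)
  expect_error(generate_oup(-1, cfg), "motion_correlation_time")
  expect_error(signal_config(1, -5), "sample_rate")
  expect_error(signal_config(1.00003, 999), "whole number")
})

test_that("single-source composite is a pure sinusoid of unit amplitude", {
  sc <- synthesize_composite(list(eod_source(827)),
                             signal_config(2, 20000, seed = 1))
  expect_lt(abs(max(abs(sc$signal$samples)) - 1), 1e-4)
  tt <- ts_times(sc$signal)
  expect_equal(sc$signal$samples, sin(2 * pi * 827 * tt), tolerance = 1e-12)
  expect_true(all(sc$amplitudes[, 1] == 1))
})

test_that("static composite is periodic with constant amplitude traces", {
  sc <- synthesize_composite(static_pair(), signal_config(4, 20000, seed = 1))
  n0 <- 20000  # EODfs are integers, so the grid period is 1 s
  expect_equal(sc$signal$samples[1:n0], sc$signal$samples[(n0 + 1):(2 * n0)],
               tolerance = 1e-8)
  expect_true(all(apply(sc$amplitudes, 2, sd) == 0))
})

test_that("composite validates sources and Nyquist", {
  cfg <- signal_config(1, 20000, seed = 1)
  expect_error(synthesize_composite(list(), cfg), "at least one")
  expect_error(
    synthesize_composite(list(eod_source(827, mean_amplitude = 0.5)), cfg),
    "receiving fish")
  expect_error(
    synthesize_composite(list(eod_source(15000)),
                         signal_config(1, 20000, seed = 1)),
    "Nyquist")
})

test_that("scene synthesis is reproducible and per-fish streams are stable", {
  cfg <- signal_config(3, 20000, seed = 11)
  a <- synthesize_composite(moving_pair(), cfg)
  b <- synthesize_composite(moving_pair(), cfg)
  expect_identical(a$signal$samples, b$signal$samples)
  # adding a third fish must not perturb fish 2's amplitude realization
  three <- c(moving_pair(),
             list(eod_source(889, 0.1, 0.5, 0.5)))
  d <- synthesize_composite(three, cfg)
  expect_identical(a$amplitudes[, 2], d$amplitudes[, 2])
})

test_that("ground-truth neighbour amplitude agrees with extracted E2", {
  sc <- synthesize_composite(moving_pair(), signal_config(10, 20000, 3))
  e2 <- extract_e2(extract_e1(sc$signal))
  gt <- neighbour_amplitude_sum(sc)
  k <- 1000  # settle window
  n <- length(e2$samples)
  expect_gt(cor(e2$samples[k:(n - k)], gt$samples[k:(n - k)]), 0.95)
})

test_that("SAM has the requested contrast independent of modulation frequency", {
  cfg <- signal_config(4, 20000, seed = 1)
  flat <- generate_sam(827, 0, 64, cfg)
  expect_lt(diff(range(attr(flat, "modulator")$samples)), 1e-12)
  c64 <- instantaneous_contrast(extract_e1(generate_sam(827, 0.3, 64, cfg)))
  c5 <- instantaneous_contrast(extract_e1(generate_sam(827, 0.3, 5, cfg)))
  expect_lt(abs(c64$mean_contrast - 0.3), 0.01)
  expect_lt(abs(c5$mean_contrast - c64$mean_contrast), 0.005)
  expect_error(generate_sam(827, 1.0, 64, cfg), "depth")
  expect_error(generate_sam(827, 0.3, 500, cfg), "half the carrier")
})

test_that("narrowband RAM is band-limited with the requested contrast", {
  cfg <- signal_config(20, 20000, seed = 6)
  ram <- generate_narrowband_ram(827, 70, 120, 0.2, cfg)
  m <- attr(ram, "modulator")$samples - 1
  expect_equal(sd(m), 0.2, tolerance = 1e-6)
  ps <- power_spectrum(time_series(m, 20000), segment_seconds = 2)
  inband <- ps$frequencies >= 69 & ps$frequencies <= 121
  expect_gt(sum(ps$power[inband]) / sum(ps$power), 0.95)
  # envelope of narrowband noise fluctuates below the band width
  env <- Mod(analytic_signal(m))
  pe <- power_spectrum(time_series(env - mean(env), 20000),
                       segment_seconds = 2)
  below <- pe$frequencies <= 50 & pe$frequencies > 0
  expect_gt(sum(pe$power[below]) / sum(pe$power[pe$frequencies > 0]), 0.8)
  # degenerate and invalid cases
  pure <- generate_narrowband_ram(827, 70, 120, 0, cfg)
  expect_equal(max(abs(pure$samples)), 1, tolerance = 1e-6)
  expect_error(generate_narrowband_ram(827, 120, 70, 0.2, cfg), "band_low")
})

test_that("text round-trip preserves a time series", {
  x <- time_series(sin(1:100), 1000)
  path <- tempfile(fileext = ".tsv")
  write_timeseries(x, path)
  y <- read_timeseries(path)
  expect_equal(y$samples, x$samples, tolerance = 1e-6)
  expect_equal(y$sample_rate, 1000, tolerance = 1e-6)
  unlink(path)
})
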