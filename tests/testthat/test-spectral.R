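# Welch PSD, spectrogram, autocorrelation + correlation-time fit, peak
# metrics and E1 period statistics.

test_that("Welch PSD satisfies Parseval and resolves a sinusoid", {
  fs <- 2000
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- time_series(sin(2 * pi * 64 * tt), fs)
  ps <- power_spectrum(x, segment_seconds = 2)
  expect_equal(psd_argmax(ps), 64, tolerance = 1e-9)
  df <- ps$frequencies[2]
  expect_lt(abs(sum(ps$power) * df - 0.5) / 0.5, 0.05)
  expect_error(power_spectrum(time_series(rnorm(100), fs),
                              segment_seconds = 2), "longer")
})

test_that("white-noise PSD is flat at the variance density", {
  fs <- 2000
  x <- time_series(withr::with_seed(2, rnorm(60 * fs)), fs)
  ps <- power_spectrum(x, segment_seconds = 2)
  expected <- 1 / (fs / 2)
  mid <- ps$frequencies > 100 & ps$frequencies < 900
  expect_lt(abs(mean(ps$power[mid]) - expected) / expected, 0.1)
  df <- ps$frequencies[2]
  expect_lt(abs(sum(ps$power) * df - 1), 0.05)
})

test_that("OUP spectrum has the Lorentzian shape", {
  lorentz <- function(f) 1 / (1 + (2 * pi * f * 0.5)^2)
  f1 <- 0.5; f2 <- 2.5
  ratios <- vapply(c(8, 18), function(s) {
    x <- generate_oup(0.5, signal_config(300, 2000, seed = s))
    ps <- power_spectrum(x, segment_seconds = 20)
    s1 <- mean(ps$power[abs(ps$frequencies - f1) <= 0.2])
    s2 <- mean(ps$power[abs(ps$frequencies - f2) <= 0.2])
    s1 / s2
  }, numeric(1))
  expected <- lorentz(f1) / lorentz(f2)
  expect_lt(abs(mean(ratios) - expected) / expected, 0.25)
})

test_that("spectrogram tracks per-fish amplitudes", {
  # amplitude step at 5 s is localized in time
  fs <- 20000
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  amp <- ifelse(tt < 5, 1, 2)
  x <- time_series(amp * sin(2 * pi * 827 * tt), fs)
  sp <- spectrogram(x, window_seconds = 0.5, step_seconds = 0.1)
  tr <- spectrogram_track(sp, 827)
  early <- tr$samples[ts_times(tr) < 4]
  late <- tr$samples[ts_times(tr) > 6]
  expect_lt(max(abs(early - 1)), 0.05)
  expect_lt(max(abs(late - 2)), 0.1)
  # static two-fish scene: both tracks constant in time
  sc <- synthesize_composite(static_pair(), signal_config(8, 20000, seed = 1))
  sp2 <- spectrogram(sc$signal, 0.5, 0.1)
  for (f in c(827, 763)) {
    trk <- spectrogram_track(sp2, f)$samples
    expect_lt(sd(trk) / mean(trk), 0.02)
  }
  expect_error(spectrogram(sc$signal, -1, 0.1), "> 0")
})

test_that("spectrogram amplitude track at the neighbour EODf follows E2", {
  sc <- synthesize_composite(moving_pair(), signal_config(20, 20000, 14))
  sp <- spectrogram(sc$signal, window_seconds = 0.5, step_seconds = 0.1)
  tr <- spectrogram_track(sp, 763)
  gt <- neighbour_amplitude_sum(sc)
  gt_w <- approx(ts_times(gt), gt$samples, xout = ts_times(tr))$y
  expect_gt(cor(tr$samples, gt_w), 0.9)
})

test_that("autocorrelation matches closed forms", {
  fs <- 2000
  wn <- time_series(withr::with_seed(3, rnorm(30 * fs)), fs)
  ac <- autocorrelation(wn, max_lag = 0.1, segment_seconds = 30)
  expect_lt(max(abs(ac$acf[-1])), 3 / sqrt(30 * fs) * 3)
  per <- time_series(sin(2 * pi * 10 * seq(0, 30, by = 1 / fs)), fs)
  acp <- autocorrelation(per, max_lag = 0.3, segment_seconds = 30)
  i <- which.min(abs(acp$lags - 0.1))
  expect_gt(acp$acf[i], 0.99)
  expect_error(autocorrelation(wn, max_lag = 40, segment_seconds = 30),
               "max_lag")
})

test_that("correlation-time fit is exact on an exponential and flags non-decay", {
  lags <- seq(0, 3, by = 1e-3)
  ac <- structure(list(lags = lags, acf = exp(-lags / 0.7), n_segments = 1),
                  class = "acf_estimate")
  fit <- fit_oup_correlation_time(ac)
  expect_true(fit$ok)
  expect_equal(fit$tau, 0.7, tolerance = 1e-3)
  flat <- structure(list(lags = lags, acf = rep(0.9, length(lags)),
                         n_segments = 1), class = "acf_estimate")
  expect_false(fit_oup_correlation_time(flat)$ok)
})

test_that("correlation-time estimates preserve the ordering of tau_c", {
  est <- function(tau, seed) {
    x <- generate_oup(tau, signal_config(120, 1000, seed = seed))
    fit_oup_correlation_time(
      autocorrelation(x, max_lag = 4 * tau, segment_seconds = 60))$tau
  }
  slow <- mean(vapply(1:3, function(s) est(2, s), numeric(1)))
  fast <- mean(vapply(1:3, function(s) est(0.2, s + 10), numeric(1)))
  expect_gt(slow, fast)
})

test_that("peak metrics recover a constructed peak and ignore distant ones", {
  f <- seq(0, 500, by = 0.5)
  gauss <- function(c0, h, w) h * exp(-(f - c0)^2 / (2 * w^2))
  spec <- structure(list(frequencies = f, power = gauss(64, 2, 3) + 1e-6,
                         segment_length = 2, n_segments = 10),
                    class = "spectral_estimate")
  pm <- peak_metrics(spec, 64, width_reference_level = 1)
  expect_equal(pm$center, 64, tolerance = 0.5)
  expect_equal(pm$height, 2, tolerance = 0.01)
  # half-height crossings of a Gaussian: full width = 2 sigma sqrt(2 ln 2)
  expect_equal(pm$width, 2 * 3 * sqrt(2 * log(2)), tolerance = 0.05)
  expect_equal(pm$resolution, pm$height / pm$width)
  # adding a second peak five-plus widths away barely moves the metrics
  spec2 <- spec
  spec2$power <- spec$power + gauss(200, 5, 3)
  pm2 <- peak_metrics(spec2, 64, width_reference_level = 1)
  expect_lt(abs(pm2$width - pm$width) / pm$width, 0.01)
  expect_lt(abs(pm2$height - pm$height) / pm$height, 0.01)
  expect_error(peak_metrics(spec, 64, width_reference_level = 5),
               "reference level")
})

test_that("E1 period statistics are exact for a noiseless beat", {
  sc <- synthesize_composite(static_pair(), signal_config(6, 20000, seed = 1))
  per <- e1_periods(extract_e1(sc$signal))
  expect_equal(per$mode, 15.63e-3, tolerance = 1e-5)
  expect_equal(mean(per$periods), 1 / 64, tolerance = 1e-4)
  expect_lt(per$cv, 0.005)
  expect_error(e1_periods(time_series(rep(1, 40000), 20000)), "crossings")
})
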