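# E1/E2 extraction, direct (peak-connection) envelope, instantaneous
# contrast, and the first-order AM theory.

test_that("E1 of a pure sinusoid is its constant amplitude", {
  sc <- synthesize_composite(list(eod_source(827)),
                             signal_config(2, 20000, seed = 1))
  e1 <- ts_trim_edges(extract_e1(sc$signal), 0.05)
  expect_lt(max(abs(e1$samples - 1)), 0.01)
  # equivariance: scaling the input scales the envelope
  scaled <- time_series(3.7 * sc$signal$samples, 20000)
  e1s <- ts_trim_edges(extract_e1(scaled), 0.05)
  expect_equal(e1s$samples, 3.7 * e1$samples, tolerance = 1e-10)
})

test_that("E1 of a static pair is dominated by the beat and free of EODf power", {
  sc <- synthesize_composite(static_pair(), signal_config(12, 20000, seed = 1))
  e1 <- ts_trim_edges(extract_e1(sc$signal))
  ps <- power_spectrum(e1)
  expect_equal(psd_argmax(ps, f_min = 1), 64, tolerance = 1e-9)
  # residual power at the EOD fundamentals at least 60 dB below the beat
  peak64 <- ps$power[which.min(abs(ps$frequencies - 64))]
  for (f in c(763, 827))
    expect_lt(ps$power[which.min(abs(ps$frequencies - f))], 1e-6 * peak64)
})

test_that("E1 recovers a known SAM modulator sample-by-sample", {
  cfg <- signal_config(4, 20000, seed = 1)
  sam <- generate_sam(827, 0.3, 64, cfg)
  e1 <- extract_e1(sam)
  truth <- attr(sam, "modulator")$samples
  k <- 1001:(length(truth) - 1000)
  expect_lt(sqrt(mean((e1$samples[k] - truth[k])^2)), 0.01)
})

test_that("E2 of a constant-amplitude beat is nearly constant", {
  sc <- synthesize_composite(static_pair(), signal_config(6, 20000, seed = 1))
  e1 <- extract_e1(sc$signal)
  e2 <- ts_trim_edges(extract_e2(e1), 0.2)
  expect_lt(sd(e2$samples) / mean(e2$samples), 0.02)
})

test_that("E2 highlights the secondary beat of a three-fish scene", {
  sc <- synthesize_composite(static_triplet(),
                             signal_config(12, 20000, seed = 1))
  env <- extract_envelopes(sc$signal)
  p2 <- power_spectrum(ts_trim_edges(env$e2))
  expect_equal(psd_argmax(p2, f_min = 5), 33, tolerance = 1e-9)
})

test_that("E2 window validation and slow-versus-fast envelope ordering hold", {
  sc <- synthesize_composite(static_pair(), signal_config(3, 20000, seed = 1))
  e1 <- extract_e1(sc$signal)
  expect_error(extract_e2(e1, window = 0.005), "beat")
  e2 <- extract_e2(e1)
  centroid <- function(x) {
    p <- power_spectrum(ts_trim_edges(x), segment_seconds = 1)
    keep <- p$frequencies > 0
    sum(p$frequencies[keep] * p$power[keep]) / sum(p$power[keep])
  }
  expect_lt(centroid(e2), centroid(e1))
})

test_that("peak-connection envelope matches the Hilbert envelope", {
  sc <- synthesize_composite(static_pair(), signal_config(6, 20000, seed = 1))
  direct <- extract_envelope_direct(sc$signal)
  hilb <- extract_e1(sc$signal)
  k <- 2001:(length(direct$samples) - 2000)
  nrms <- sqrt(mean((direct$samples[k] - hilb$samples[k])^2)) /
    mean(hilb$samples[k])
  expect_lt(nrms, 0.05)
  # known-modulator tracking at heavy depth
  sam <- generate_sam(827, 0.5, 20, signal_config(3, 20000, seed = 1))
  dsam <- extract_envelope_direct(sam)
  truth <- attr(sam, "modulator")$samples
  k <- 2001:(length(truth) - 2000)
  expect_lt(max(abs(dsam$samples[k] - truth[k])), 0.02 * max(truth))
  expect_error(extract_envelope_direct(time_series(1:100, 100)), "maxima")
})

test_that("instantaneous contrast equals SAM depth across depths", {
  cfg <- signal_config(4, 20000, seed = 1)
  for (M in c(0.05, 0.1, 0.3, 0.5)) {
    cs <- instantaneous_contrast(extract_e1(generate_sam(827, M, 64, cfg)))
    expect_lt(abs(cs$mean_contrast - M) / M, 0.01)
    expect_lt(cs$sd_contrast, 0.01)
  }
  # a constant envelope has no extrema to pair
  expect_error(instantaneous_contrast(time_series(rep(1, 4000), 20000)),
               "extrema|pairs|max")
})

test_that("contrast statistics of a moving pair follow the first-order theory", {
  # single-seed sanity; the multi-seed comparison runs in the acceptance suite
  sc <- synthesize_composite(moving_pair(), signal_config(60, 20000, 7))
  cs <- instantaneous_contrast(extract_e1(sc$signal))
  pred <- predict_am(sc$sources)
  expect_lt(abs(cs$mean_contrast - pred$mean_contrast) / pred$mean_contrast,
            0.2)
  expect_lt(abs(cs$sd_contrast - pred$sd_contrast) / pred$sd_contrast, 0.3)
  # contrast is scale-invariant
  cs2 <- instantaneous_contrast(
    extract_e1(time_series(2.5 * sc$signal$samples, 20000)))
  expect_equal(cs2$mean_contrast, cs$mean_contrast, tolerance = 1e-8)
})

test_that("predict_am returns the Taylor-order contrast pair", {
  pred <- predict_am(moving_pair(a2 = 0.143, sigma2 = 0.56))
  expect_equal(pred$mean_contrast, 0.143)
  expect_equal(pred$sd_contrast, 0.143 * 0.56)
  expect_equal(pred$beat_frequency, 64)
  expect_equal(predict_am(moving_pair(sigma2 = 0))$sd_contrast, 0)
  expect_warning(predict_am(static_pair(a2 = 0.6)), "Taylor")
  expect_error(predict_am(list(eod_source(827))), "two-fish")
})
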