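# LIFDT P-unit: simulation contracts, P-value arithmetic, calibration on
# both heterogeneity axes, population sampling and rates.

test_that("silent and deterministic limits behave", {
  quiet <- time_series(numeric(20000), 100000)
  st <- simulate_punit(quiet, lifdt_params(noise_intensity = 0), seed = 1)
  expect_length(st$spike_times, 0)
  expect_equal(compute_p_value(st, 827), 0)
  base <- baseline_stimulus(827, 2)
  a <- simulate_punit(base, lifdt_params(), seed = 5)
  b <- simulate_punit(base, lifdt_params(), seed = 5)
  expect_identical(a$spike_times, b$spike_times)
  c2 <- simulate_punit(base, lifdt_params(), seed = 6)
  expect_false(identical(a$spike_times, c2$spike_times))
})

test_that("spike trains respect the integration grid and rate bound", {
  base <- baseline_stimulus(827, 5)
  st <- simulate_punit(base, lifdt_params(noise_intensity = 1), seed = 2)
  expect_true(all(diff(st$spike_times) >= st$time_step / 1000 - 1e-12))
  expect_true(all(st$spike_times >= 0 & st$spike_times <= st$duration))
  # across the physiological drive range the unit fires at most about
  # once per EOD cycle
  loud <- time_series(1.2 * base$samples, base$sample_rate)
  st2 <- simulate_punit(loud, lifdt_params(noise_intensity = 1), seed = 2)
  expect_lt(compute_p_value(st2, 827), 1)
})

test_that("P-value arithmetic is spike count over duration over EODf", {
  st <- structure(list(spike_times = seq(0, 0.999, length.out = 215),
                       duration = 1, time_step = 0.01),
                  class = "spike_train")
  expect_equal(compute_p_value(st, 827), 215 / 827)
  expect_equal(round(compute_p_value(st, 827), 3), 0.260)
  empty <- structure(list(spike_times = numeric(0), duration = 1,
                          time_step = 0.01), class = "spike_train")
  expect_equal(compute_p_value(empty, 827), 0)
})

test_that("baseline firing is stationary and phase-locked", {
  u <- calibrate_noise_for_pvalue(0.26)
  p10 <- compute_p_value(simulate_punit(baseline_stimulus(827, 10), u, 31),
                         827)
  p20 <- compute_p_value(simulate_punit(baseline_stimulus(827, 20), u, 32),
                         827)
  expect_lt(abs(p10 - p20), 0.02)
  st <- simulate_punit(baseline_stimulus(827, 10), u, 33)
  expect_gt(vector_strength(st, 827), 0.3)
})

test_that("firing rate increases with stimulus amplitude", {
  u <- calibrate_noise_for_pvalue(0.26)
  rates <- vapply(c(0.8, 0.9, 1.0, 1.1, 1.2), function(a) {
    stim <- baseline_stimulus(827, 4)
    st <- simulate_punit(time_series(a * stim$samples, stim$sample_rate),
                         u, seed = 7)
    length(st$spike_times) / st$duration
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("rate follows a slow SAM cycle", {
  sam <- generate_sam(827, 0.2, 5, signal_config(20, 100000, seed = 3))
  u <- calibrate_noise_for_pvalue(0.26)
  st <- simulate_punit(sam, u, seed = 8)
  rate <- spikes_to_rate(st, bin = 5e-3, demean = TRUE)
  ps <- power_spectrum(rate, segment_seconds = 2)
  expect_equal(psd_argmax(ps, f_min = 1), 5, tolerance = 0.5)
})

test_that("noise calibration hits targets and is monotone", {
  for (target in c(0.12, 0.26, 0.40)) {
    u <- calibrate_noise_for_pvalue(target)
    expect_lt(abs(attr(u, "realized_p") - target), 0.01)
  }
  d12 <- calibrate_noise_for_pvalue(0.12)$noise_intensity
  d40 <- calibrate_noise_for_pvalue(0.40)$noise_intensity
  expect_gt(d40, d12)
  expect_error(calibrate_noise_for_pvalue(0.9), "target_p")
  expect_error(calibrate_noise_for_pvalue(0.3, d_bounds = c(1e-6, 1e-5)),
               "unreachable")
})

test_that("threshold calibration hits targets with opposite monotonicity", {
  for (target in c(0.12, 0.40)) {
    u <- calibrate_threshold_for_pvalue(target)
    expect_lt(abs(attr(u, "realized_p") - target), 0.01)
  }
  th12 <- calibrate_threshold_for_pvalue(0.12)$threshold_baseline
  th40 <- calibrate_threshold_for_pvalue(0.40)$threshold_baseline
  expect_gt(th12, th40)  # less excitable unit fires on fewer cycles
})

test_that("a small population samples within bounds reproducibly", {
  pop <- sample_population(8, master_seed = 5, duration = 10)
  p <- realized_p_values(pop)
  expect_true(all(p >= 0.08 & p <= 0.62))
  expect_true(all(vapply(pop$units, function(u)
    abs(u$realized_p - u$target_p) < 0.015, logical(1))))
  pop2 <- sample_population(1, master_seed = 5, duration = 10)
  pop3 <- sample_population(1, master_seed = 5, duration = 10)
  expect_identical(pop2$units[[1]]$params$noise_intensity,
                   pop3$units[[1]]$params$noise_intensity)
})

test_that("population rate is flat for a baseline stimulus", {
  pop <- sample_population(6, master_seed = 9, duration = 10)
  base <- baseline_stimulus(827, 6)
  rate <- population_rate(pop, base, seed = 10)
  expect_lt(sd(rate$samples) / mean(rate$samples), 0.1)
  expect_error(population_rate(pop, base, window = 5e-4), "EOD cycle")
})

test_that("spike binning conserves counts and stimulus rate mismatch is explicit", {
  base <- baseline_stimulus(827, 3)
  st <- simulate_punit(base, lifdt_params(), seed = 4)
  r <- spikes_to_rate(st, bin = 5e-4, demean = FALSE)
  expect_equal(sum(r$samples) * 5e-4, length(st$spike_times))
  low <- time_series(sin(2 * pi * 827 * seq(0, 1, by = 1 / 20000)), 20000)
  expect_message(simulate_punit(low, lifdt_params(), seed = 1), "resampling")
})
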