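#' Experiment configuration
#'
#' Bundles every setting of an end-to-end analysis so a run is fully
#' reproducible from the config and master seed alone.
#'
#' @param sources list of [eod_source()] (receiving fish first).
#' @param duration record length in seconds.
#' @param sample_rate sampling rate in Hz (100 kHz for encoding runs, which
#'   matches the 0.01 ms P-unit step; 20 kHz is adequate for envelope-only
#'   analyses).
#' @param seed master seed; all stage seeds are fanned out from it with
#'   [child_seed()].
#' @param lpf_cutoff E1 low-pass cutoff (Hz).
#' @param e2_window E2 window (s).
#' @param segment_seconds,overlap_fraction Welch settings.
#' @param p_values target P-values for single-unit encoding analyses.
#' @param population_n heterogeneous population size.
#' @param mi_band motion band for MI rates (Hz).
#' @param base_params [lifdt_params()] template for P-units.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sources = two_fish_scene(),
                              duration = 12, sample_rate = 20000, seed = 1,
                              lpf_cutoff = 200, e2_window = 0.1,
                              segment_seconds = 2, overlap_fraction = 0.5,
                              p_values = c(0.12, 0.26, 0.40),
                              population_n = 200, mi_band = c(0, 20),
                              base_params = lifdt_params()) {
  structure(
    list(sources = sources, duration = duration, sample_rate = sample_rate,
         seed = as.integer(seed), lpf_cutoff = lpf_cutoff,
         e2_window = e2_window, segment_seconds = segment_seconds,
         overlap_fraction = overlap_fraction, p_values = p_values,
         population_n = population_n, mi_band = mi_band,
         base_params = base_params),
    class = "experiment_config"
  )
}

# expected primary beats (|f1 - fn|) and secondary beats (differences
# between primary beats) of a scene
scene_beats <- function(sources) {
  f <- vapply(sources, `[[`, numeric(1), "eod_frequency")
  primary <- abs(f[-1] - f[1])
  secondary <- if (length(primary) > 1L)
    abs(as.numeric(stats::dist(primary))) else numeric(0)
  list(primary = primary, secondary = secondary)
}

provenance <- function(config, stage) {
  list(stage = stage, seed = config$seed,
       package_version = as.character(utils::packageVersion("eodcoding")),
       config_digest = sum(utf8ToInt(paste(deparse(config), collapse = ""))))
}

#' Full scene (signal and envelope) analysis
#'
#' Synthesizes the configured scene and computes: PSDs of the raw signal,
#' E1 and E2; beat-peak metrics for every expected primary beat and the
#' strongest secondary-beat peak of E2; instantaneous-contrast statistics;
#' E2 autocorrelation with OUP correlation-time fit; E1 period statistics;
#' and the 0-20 Hz motion-floor band power of E1.
#'
#' @param config an [experiment_config()].
#' @return A list bundle; see elements `summary`, `psd`, `envelopes`,
#'   `scene`.
#' @export
run_scene_analysis <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("run_scene_analysis [", stage, "]: ", conditionMessage(e),
           call. = FALSE))
  }
  scene <- run_stage("synthesize", synthesize_composite(
    config$sources, signal_config(config$duration, config$sample_rate,
                                  config$seed)))
  env <- run_stage("envelopes", extract_envelopes(
    scene$signal, config$lpf_cutoff, config$e2_window))
  psd_s <- run_stage("psd", power_spectrum(
    scene$signal, config$segment_seconds, config$overlap_fraction))
  psd_e1 <- run_stage("psd", power_spectrum(
    ts_trim_edges(env$e1), config$segment_seconds, config$overlap_fraction))
  psd_e2 <- run_stage("psd", power_spectrum(
    ts_trim_edges(env$e2), config$segment_seconds, config$overlap_fraction))
  beats <- scene_beats(config$sources)
  beat_peaks <- lapply(beats$primary, function(b)
    run_stage("peaks", peak_metrics(psd_e1, b)))
  # strongest E2 component above 5 Hz (secondary beat for >= 3 fish)
  above5 <- psd_e2$frequencies > 5
  e2_peak_frequency <- psd_e2$frequencies[above5][
    which.max(psd_e2$power[above5])]
  contrast <- run_stage("contrast", instantaneous_contrast(env$e1))
  ac <- run_stage("autocorrelation", autocorrelation(
    ts_trim_edges(env$e2), max_lag = min(3, ts_duration(env$e2) / 4)))
  tau_fit <- run_stage("tau_fit", fit_oup_correlation_time(ac))
  periods <- run_stage("periods", e1_periods(env$e1))
  motion_floor <- run_stage("band_power", band_power(psd_e1, 0, 20))
  list(
    scene = scene, envelopes = env,
    psd = list(signal = psd_s, e1 = psd_e1, e2 = psd_e2),
    autocorrelation = ac,
    summary = list(
      beat_frequencies = beats$primary,
      secondary_beats = beats$secondary,
      beat_peaks = beat_peaks,
      e2_peak_frequency = e2_peak_frequency,
      mean_contrast = contrast$mean_contrast,
      sd_contrast = contrast$sd_contrast,
      tau_c_estimate = tau_fit$tau,
      period_mode = periods$mode,
      period_cv = periods$cv,
      motion_floor_power = motion_floor),
    contrast = contrast, periods = periods, tau_fit = tau_fit,
    provenance = provenance(config, "scene_analysis")
  )
}

#' Single-unit and population encoding analysis
#'
#' Synthesizes the scene at the P-unit integration rate, calibrates one
#' unit per requested P-value, and computes: spike-train PSDs, E1-response
#' and E2-response coherences (with beat-peak metrics and motion-band
#' statistics), MI rates over the motion band, and the windowed
#' population-rate correlation with E2.
#'
#' @param config an [experiment_config()]; `sample_rate` should be
#'   `1000 / base_params$time_step` (100 kHz by default).
#' @param population_n override for the population size (`NULL` uses the
#'   config; set 0 to skip the population stage).
#' @return A list bundle; see element `summary`.
#' @export
run_encoding_analysis <- function(config, population_n = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(population_n)) population_n <- config$population_n
  scene <- synthesize_composite(
    config$sources, signal_config(config$duration, config$sample_rate,
                                  config$seed))
  env <- extract_envelopes(scene$signal, config$lpf_cutoff, config$e2_window)
  beats <- scene_beats(config$sources)
  eodf <- config$sources[[1]]$eod_frequency
  units <- lapply(config$p_values, function(p)
    calibrate_noise_for_pvalue(p, eodf, config$base_params,
                               calibration_seed = child_seed(config$seed,
                                                             940000 + round(1000 * p))))
  per_unit <- vector("list", length(units))
  for (i in seq_along(units)) {
    st <- simulate_punit(scene$signal, units[[i]],
                         seed = child_seed(config$seed, 950000 + i))
    rate <- spikes_to_rate(st)
    psd_r <- power_spectrum(rate, config$segment_seconds,
                            config$overlap_fraction)
    coh_e1 <- envelope_response_coherence(env$e1, st, config$segment_seconds,
                                          config$overlap_fraction)
    coh_e2 <- envelope_response_coherence(env$e2, st, config$segment_seconds,
                                          config$overlap_fraction)
    peak <- tryCatch(
      coherence_peak_metrics(coh_e1, beats$primary[1]),
      error = function(e) NULL)
    per_unit[[i]] <- list(
      target_p = config$p_values[i],
      realized_p = attr(units[[i]], "realized_p"),
      spike_train = st, psd = psd_r,
      coherence_e1 = coh_e1, coherence_e2 = coh_e2,
      e1_peak = peak,
      e2_band_coherence = band_coherence(coh_e2, config$mi_band[1],
                                         config$mi_band[2]),
      mi_e2 = mutual_info_rate(coh_e2, config$mi_band[1], config$mi_band[2]))
  }
  pop <- NULL
  if (population_n > 0) {
    pop_obj <- sample_population(population_n, eodf,
                                 master_seed = child_seed(config$seed, 960000),
                                 base_params = config$base_params)
    prate <- population_rate(pop_obj, scene$signal,
                             seed = child_seed(config$seed, 970000))
    e2_w <- window_means(env$e2, 1 / prate$sample_rate)
    n <- min(length(e2_w), length(prate$samples))
    pop <- list(population = pop_obj, rate = prate,
                e2_correlation = stats::cor(prate$samples[seq_len(n)],
                                            e2_w[seq_len(n)]))
  }
  list(
    scene = scene, envelopes = env, units = per_unit, population = pop,
    summary = list(
      beat_frequencies = beats$primary,
      e1_coherence_peak_frequencies = vapply(per_unit, function(u)
        if (is.null(u$e1_peak)) NA_real_ else u$e1_peak$center, numeric(1)),
      e2_band_coherence = vapply(per_unit, `[[`, numeric(1),
                                 "e2_band_coherence"),
      mi_rates = vapply(per_unit, function(u) u$mi_e2$rate, numeric(1)),
      population_e2_correlation = if (is.null(pop)) NA_real_
                                  else pop$e2_correlation),
    provenance = provenance(config, "encoding_analysis")
  )
}

# mean of a series over consecutive windows of `window` seconds
window_means <- function(x, window) {
  w <- as.integer(round(window * x$sample_rate))
  n <- length(x$samples) %/% w
  colMeans(matrix(x$samples[seq_len(n * w)], nrow = w))
}

#' Parameter sweep with trend summary
#'
#' Re-runs the scene (and optionally encoding) analysis over a grid of one
#' parameter, averaging each metric over seed replicates, and reports the
#' sign of the Spearman correlation between the parameter and each metric.
#'
#' Supported parameters: `"A2"` (neighbour mean amplitude, i.e. mean
#' contrast; the sweep holds the scene's ABSOLUTE contrast SD
#' \eqn{A_2\sigma_2} fixed at its config value, so the relative
#' fluctuation scale falls as `A2` rises — this is the parameterization
#' under which tank-scale sweeps report their amplitude trends, and it
#' matches the contrast convention in which pairs are characterized),
#' `"sigma2"` (relative fluctuation scale at the config's `A2`; at fixed
#' `A2` this is a pure rescale of the contrast SD, so trends are
#' identical in either convention), `"tau_c"` (motion correlation time),
#' and `"p_value"` (P-unit P-value against a narrowband RAM stimulus, the
#' laboratory control: metrics are the maximum RAM-response coherence in
#' the RAM band and the maximum envelope-response coherence in the slow
#' band).
#'
#' @param config an [experiment_config()] (two-fish scene for the scene
#'   parameters).
#' @param parameter one of `"A2"`, `"sigma2"`, `"tau_c"`, `"p_value"`.
#' @param values parameter grid (>= 3 values; >= 5 for a meaningful trend).
#' @param replicates seed replicates per value (default 5; the tank-scale
#'   analyses average 50).
#' @param encoding also compute encoding metrics (coherence-peak ratio at
#'   the beat and motion-band MI); slower.  Ignored for `"p_value"`.
#' @param ram_band,ram_contrast narrowband-RAM settings for the
#'   `"p_value"` sweep.
#' @return A data.frame of per-value mean metrics plus attribute
#'   `"trends"`, the sign of the Spearman correlation per metric.
#' @export
run_parameter_sweep <- function(config, parameter, values, replicates = 5,
                                encoding = FALSE, ram_band = c(70, 120),
                                ram_contrast = 0.2) {
  stopifnot(inherits(config, "experiment_config"))
  parameter <- match.arg(parameter, c("A2", "sigma2", "tau_c", "p_value"))
  if (parameter == "p_value")
    return(ram_pvalue_sweep(config, values, replicates, ram_band,
                            ram_contrast))
  rows <- vector("list", length(values))
  # common width-reference level for peak metrics across the whole sweep,
  # anchored at the first condition so widths are comparable
  ref_level <- NULL
  ref_unit <- if (encoding)
    calibrate_noise_for_pvalue(
      0.26, config$sources[[1]]$eod_frequency, config$base_params,
      calibration_seed = child_seed(config$seed, 980000))
  for (vi in seq_along(values)) {
    acc <- list()
    for (rep in seq_len(replicates)) {
      cfg <- config
      # common random numbers: each replicate reuses one noise realization
      # across every parameter value, so value-to-value differences reflect
      # the parameter, not the draw (the tank-scale sweeps reuse their OU
      # realizations across settings the same way)
      cfg$seed <- child_seed(config$seed, 1000 + rep)
      s2 <- cfg$sources[[2]]
      if (parameter == "A2") {
        # hold the absolute contrast SD of the config fixed
        sd_abs <- s2$mean_amplitude * s2$amplitude_sd
        s2$mean_amplitude <- values[vi]
        s2$amplitude_sd <- sd_abs / values[vi]
      }
      if (parameter == "sigma2") s2$amplitude_sd <- values[vi]
      if (parameter == "tau_c") s2$motion_correlation_time <- values[vi]
      cfg$sources[[2]] <- s2
      scene <- synthesize_composite(
        cfg$sources, signal_config(cfg$duration, cfg$sample_rate, cfg$seed))
      env <- extract_envelopes(scene$signal, cfg$lpf_cutoff, cfg$e2_window)
      psd_e1 <- power_spectrum(ts_trim_edges(env$e1), cfg$segment_seconds,
                               cfg$overlap_fraction)
      beat <- scene_beats(cfg$sources)$primary[1]
      if (is.null(ref_level))
        ref_level <- 10 * spectral_floor(psd_e1, beat)
      pk <- peak_metrics(psd_e1, beat, width_reference_level = ref_level)
      per <- e1_periods(env$e1)
      row <- list(peak_height = pk$height, peak_width = pk$width,
                  peak_resolution = pk$resolution, period_cv = per$cv)
      if (encoding) {
        st <- simulate_punit(scene$signal, ref_unit,
                             seed = child_seed(cfg$seed, 990000))
        coh_e1 <- envelope_response_coherence(env$e1, st, cfg$segment_seconds,
                                              cfg$overlap_fraction)
        coh_e2 <- envelope_response_coherence(env$e2, st, cfg$segment_seconds,
                                              cfg$overlap_fraction)
        cpk <- tryCatch(coherence_peak_metrics(coh_e1, beat),
                        error = function(e) NULL)
        row$coherence_peak_ratio <- if (is.null(cpk)) NA_real_
                                    else cpk$resolution
        row$mi_motion <- mutual_info_rate(coh_e2, cfg$mi_band[1],
                                          cfg$mi_band[2])$rate
      }
      acc[[rep]] <- row
    }
    mets <- names(acc[[1]])
    rows[[vi]] <- c(list(value = values[vi]),
                    lapply(stats::setNames(mets, mets), function(m)
                      mean(vapply(acc, function(a) a[[m]], numeric(1)),
                           na.rm = TRUE)))
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  metric_cols <- setdiff(names(out), "value")
  trends <- vapply(metric_cols, function(m)
    sign(stats::cor(out$value, out[[m]], method = "spearman")), numeric(1))
  attr(out, "trends") <- trends
  out
}

# P-value sweep against a narrowband RAM: how unit excitability trades off
# carrier-band (RAM) versus envelope coding.  Units are tuned along the
# excitability axis (threshold baseline at fixed small noise): the P-value
# heterogeneity of this control reflects how ready a unit is to fire, and
# under it higher-P units track the fast carrier-band modulation better
# while lower-P units demodulate the envelope better.
ram_pvalue_sweep <- function(config, p_values, replicates, ram_band,
                             ram_contrast) {
  eodf <- config$sources[[1]]$eod_frequency
  env_band <- c(0, ram_band[2] - ram_band[1])
  rows <- vector("list", length(p_values))
  units <- lapply(p_values, function(p)
    calibrate_threshold_for_pvalue(p, eodf,
                                   calibration_seed = child_seed(config$seed,
                                                                 940000 + round(1000 * p))))
  for (vi in seq_along(p_values)) {
    ram_c <- numeric(replicates); env_c <- numeric(replicates)
    for (rep in seq_len(replicates)) {
      seed <- child_seed(config$seed, 5000 + vi * 100 + rep)
      cfg <- signal_config(config$duration, config$sample_rate, seed)
      stim <- generate_narrowband_ram(eodf, ram_band[1], ram_band[2],
                                      ram_contrast, cfg)
      st <- simulate_punit(stim, units[[vi]],
                           seed = child_seed(seed, 991000))
      mod <- attr(stim, "modulator")
      coh_ram <- envelope_response_coherence(mod, st, config$segment_seconds,
                                             config$overlap_fraction)
      # envelope of the narrowband modulation itself (power below the
      # band width), not of the offset carrier-side modulator
      menv <- extract_e1(
        time_series(mod$samples - mean(mod$samples), mod$sample_rate),
        lpf_cutoff = ram_band[2] - ram_band[1])
      coh_env <- envelope_response_coherence(menv, st,
                                             config$segment_seconds,
                                             config$overlap_fraction)
      in_ram <- coh_ram$frequencies >= ram_band[1] &
        coh_ram$frequencies <= ram_band[2]
      in_env <- coh_env$frequencies > 0 &
        coh_env$frequencies <= env_band[2]
      ram_c[rep] <- max(coh_ram$coherence[in_ram])
      env_c[rep] <- max(coh_env$coherence[in_env])
    }
    rows[[vi]] <- data.frame(value = p_values[vi],
                             ram_coherence = mean(ram_c),
                             envelope_coherence = mean(env_c))
  }
  out <- do.call(rbind, rows)
  trends <- c(
    ram_coherence = sign(stats::cor(out$value, out$ram_coherence,
                                    method = "spearman")),
    envelope_coherence = sign(stats::cor(out$value, out$envelope_coherence,
                                         method = "spearman")))
  attr(out, "trends") <- trends
  out
}
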