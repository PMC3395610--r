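#' EOD source specification for one fish
#'
#' Describes one fish's contribution to the composite signal received by the
#' "receiving" fish: a sinusoid at the fish's electric-organ-discharge
#' frequency (EODf) whose amplitude, for moving neighbours, fluctuates as a
#' scaled Ornstein-Uhlenbeck process (OUP),
#' \eqn{A_n (1 + \sigma_n \xi_n(t))}.
#'
#' @param eod_frequency EOD fundamental frequency in Hz (> 0).
#' @param mean_amplitude mean amplitude \eqn{A_n} relative to the receiving
#'   fish (whose amplitude is fixed at 1).
#' @param amplitude_sd relative fluctuation scale \eqn{\sigma_n} (the
#'   coefficient of variation of the amplitude); 0 for a static fish.
#' @param motion_correlation_time OUP correlation time \eqn{\tau_c} in
#'   seconds, setting the time scale of motion-induced amplitude change.
#' @param phase phase offset in radians (default 0; phase does not affect
#'   the envelope spectra analysed here).
#' @return An object of class `eod_source`.
#' @export
eod_source <- function(eod_frequency, mean_amplitude = 1, amplitude_sd = 0,
                       motion_correlation_time = 0.5, phase = 0) {
  if (eod_frequency <= 0) stop("eod_source: eod_frequency must be > 0")
  if (mean_amplitude < 0) stop("eod_source: mean_amplitude must be >= 0")
  if (amplitude_sd < 0) stop("eod_source: amplitude_sd must be >= 0")
  if (motion_correlation_time <= 0)
    stop("eod_source: motion_correlation_time must be > 0")
  structure(
    list(eod_frequency = eod_frequency, mean_amplitude = mean_amplitude,
         amplitude_sd = amplitude_sd,
         motion_correlation_time = motion_correlation_time, phase = phase),
    class = "eod_source"
  )
}

#' Signal synthesis configuration
#'
#' @param duration record length in seconds; `duration * sample_rate` must
#'   be a whole number of samples.
#' @param sample_rate sampling rate in Hz.  100 kHz matches the recording
#'   rate used in tank experiments and the 0.01 ms P-unit integration step;
#'   20 kHz is a fast mode adequate for envelope-only analyses.
#' @param seed RNG seed for all stochastic components of the scene.
#' @return An object of class `signal_config`.
#' @export
signal_config <- function(duration, sample_rate = 100000, seed = 1) {
  if (duration <= 0) stop("signal_config: duration must be > 0")
  if (sample_rate <= 0) stop("signal_config: sample_rate must be > 0")
  n <- duration * sample_rate
  if (abs(n - round(n)) > 1e-6)
    stop("signal_config: duration * sample_rate must be a whole number of samples")
  structure(
    list(duration = duration, sample_rate = sample_rate,
         seed = as.integer(seed), n_samples = as.integer(round(n))),
    class = "signal_config"
  )
}

#' Generate an Ornstein-Uhlenbeck process
#'
#' Zero-mean, unit-variance stationary OUP with autocorrelation
#' \eqn{\exp(-|\Delta t| / \tau_c)}, modelling the slow amplitude
#' fluctuation produced by a swimming fish.  Uses the exact AR(1)
#' discretization
#' \eqn{\xi_{k+1} = \alpha \xi_k + \sqrt{1 - \alpha^2}\, w_k},
#' \eqn{\alpha = e^{-\Delta t/\tau_c}}, so the stationary unit variance
#' holds at any step size; the initial value is drawn from the stationary
#' distribution.
#'
#' @param motion_correlation_time correlation time \eqn{\tau_c} in seconds.
#' @param config a [signal_config()]; its seed makes the draw reproducible.
#' @return A [time_series()] of the process.
#' @export
generate_oup <- function(motion_correlation_time, config) {
  if (!is.numeric(motion_correlation_time) || motion_correlation_time <= 0)
    stop("generate_oup: motion_correlation_time must be > 0")
  stopifnot(inherits(config, "signal_config"))
  n <- config$n_samples
  a <- exp(-1 / (config$sample_rate * motion_correlation_time))
  s <- sqrt(1 - a^2)
  x <- local_seed(config$seed, {
    innov <- c(stats::rnorm(1), s * stats::rnorm(n - 1))
    as.numeric(stats::filter(innov, a, method = "recursive"))
  })
  time_series(x, config$sample_rate)
}

#' Build a two-fish scene from contrast statistics
#'
#' Convenience constructor for the canonical receiving-fish + one-neighbour
#' configuration.  Tank recordings characterize a pair by the mean and SD
#' of the instantaneous contrast of the received amplitude modulation; to
#' first order these equal \eqn{A_2} and \eqn{A_2 \sigma_2}.  The default
#' `convention = "contrast"` therefore maps a printed pair (mean, SD) to
#' \eqn{A_2 = } mean and \eqn{\sigma_2 = } SD/mean;
#' `convention = "amplitude"` instead reads the pair directly as
#' \eqn{(A_2, \sigma_2)}.
#'
#' @param f1,f2 EOD frequencies (Hz) of the receiving fish and neighbour.
#' @param mean_contrast,contrast_sd the pair characterizing the neighbour
#'   (defaults 0.143 and 0.08, a representative moving pair).
#' @param convention how to interpret the pair (see Details).
#' @param motion_correlation_time OUP correlation time in seconds.
#' @return List of two [eod_source()] objects (receiving fish first).
#' @export
two_fish_scene <- function(f1 = 827, f2 = 763, mean_contrast = 0.143,
                           contrast_sd = 0.08,
                           convention = c("contrast", "amplitude"),
                           motion_correlation_time = 0.5) {
  convention <- match.arg(convention)
  if (convention == "contrast") {
    a2 <- mean_contrast
    sigma2 <- if (contrast_sd > 0) contrast_sd / mean_contrast else 0
  } else {
    a2 <- mean_contrast
    sigma2 <- contrast_sd
  }
  list(
    eod_source(f1, mean_amplitude = 1, amplitude_sd = 0),
    eod_source(f2, mean_amplitude = a2, amplitude_sd = sigma2,
               motion_correlation_time = motion_correlation_time)
  )
}

#' Synthesize the composite multi-fish EOD signal
#'
#' Builds
#' \deqn{S(t) = \sum_n A_n (1 + \sigma_n \xi_n(t)) \sin(2\pi f_n t + \phi_n)}
#' with an independent OUP \eqn{\xi_n} per moving fish.  The first source is
#' the receiving fish and must have `mean_amplitude = 1`,
#' `amplitude_sd = 0`.  Per-fish RNG streams are derived from the config
#' seed by fixed offsets, so the realization for fish n does not change
#' when fish are added.  Instantaneous amplitudes are not clipped at zero:
#' large \eqn{\sigma_n} can drive them negative, and envelope analysis
#' treats the magnitude.
#'
#' @param sources list of [eod_source()] (receiving fish first).
#' @param config a [signal_config()].  All EODfs must be below Nyquist.
#' @return An object of class `eod_scene`: a list with `signal` (the
#'   composite [time_series()]), `amplitudes` (matrix of per-source
#'   ground-truth amplitude traces \eqn{A_n(1+\sigma_n\xi_n(t))}),
#'   `sources` and `config`.
#' @export
synthesize_composite <- function(sources, config) {
  stopifnot(inherits(config, "signal_config"))
  if (length(sources) < 1L) stop("synthesize_composite: need at least one source")
  if (!all(vapply(sources, inherits, logical(1), "eod_source")))
    stop("synthesize_composite: sources must be eod_source objects")
  f <- vapply(sources, `[[`, numeric(1), "eod_frequency")
  if (config$sample_rate <= 2 * max(f))
    stop("synthesize_composite: sample rate violates Nyquist for EODf ",
         max(f), " Hz")
  s1 <- sources[[1]]
  if (s1$mean_amplitude != 1 || s1$amplitude_sd != 0)
    stop("synthesize_composite: first source is the receiving fish and must ",
         "have mean_amplitude = 1 and amplitude_sd = 0")
  n <- config$n_samples
  tt <- (seq_len(n) - 1) / config$sample_rate
  amp <- matrix(0, n, length(sources))
  sig <- numeric(n)
  for (k in seq_along(sources)) {
    src <- sources[[k]]
    a <- rep(src$mean_amplitude, n)
    if (src$amplitude_sd > 0) {
      sub <- signal_config(config$duration, config$sample_rate,
                           seed = child_seed(config$seed, k))
      xi <- generate_oup(src$motion_correlation_time, sub)
      a <- src$mean_amplitude * (1 + src$amplitude_sd * xi$samples)
    }
    amp[, k] <- a
    sig <- sig + a * sin(2 * pi * src$eod_frequency * tt + src$phase)
  }
  structure(
    list(signal = time_series(sig, config$sample_rate),
         amplitudes = amp, sources = sources, config = config),
    class = "eod_scene"
  )
}

#' @export
print.eod_scene <- function(x, ...) {
  f <- vapply(x$sources, `[[`, numeric(1), "eod_frequency")
  cat(sprintf("<eod_scene: %d fish (EODf %s Hz), %g s @ %g Hz, seed %d>\n",
              length(x$sources), paste(f, collapse = "/"),
              x$config$duration, x$config$sample_rate, x$config$seed))
  invisible(x)
}

#' Summed ground-truth amplitude of the neighbouring fish
#'
#' @param scene an `eod_scene` from [synthesize_composite()].
#' @return A [time_series()] of \eqn{\sum_{n \ge 2} A_n(1+\sigma_n\xi_n(t))},
#'   the quantity the second envelope E2 tracks (up to an offset).
#' @export
neighbour_amplitude_sum <- function(scene) {
  stopifnot(inherits(scene, "eod_scene"))
  if (ncol(scene$amplitudes) < 2L)
    stop("neighbour_amplitude_sum: scene has no neighbours")
  time_series(rowSums(scene$amplitudes[, -1, drop = FALSE]),
              scene$signal$sample_rate)
}

#' Generate a sinusoidally amplitude-modulated carrier (SAM)
#'
#' \eqn{(1 + M \sin(2\pi f_m t)) \sin(2\pi f_c t)}: the standard laboratory
#' mimic of a static conspecific.  The contrast (coefficient of variation)
#' of its amplitude modulation equals the depth \eqn{M}.
#'
#' @param carrier_frequency carrier (EOD) frequency \eqn{f_c} in Hz.
#' @param depth modulation depth \eqn{M \in [0, 1)}; `depth >= 1` would
#'   rectify the envelope and is rejected.
#' @param modulation_frequency \eqn{f_m} in Hz; must be below
#'   `carrier_frequency / 2`.
#' @param config a [signal_config()].
#' @return A [time_series()] with the modulator \eqn{1 + M\sin(2\pi f_m t)}
#'   attached as attribute `"modulator"`.
#' @export
generate_sam <- function(carrier_frequency, depth, modulation_frequency,
                         config) {
  stopifnot(inherits(config, "signal_config"))
  if (depth < 0 || depth >= 1)
    stop("generate_sam: depth must be in [0, 1)")
  if (modulation_frequency >= carrier_frequency / 2)
    stop("generate_sam: modulation frequency must be below half the carrier")
  if (config$sample_rate <= 2 * carrier_frequency)
    stop("generate_sam: Nyquist violation")
  tt <- (seq_len(config$n_samples) - 1) / config$sample_rate
  m <- 1 + depth * sin(2 * pi * modulation_frequency * tt)
  out <- time_series(m * sin(2 * pi * carrier_frequency * tt),
                     config$sample_rate)
  attr(out, "modulator") <- time_series(m, config$sample_rate)
  out
}

#' Generate a narrowband random-amplitude-modulated carrier (RAM)
#'
#' Carrier multiplied by \eqn{1 + m(t)} with \eqn{m(t)} zero-mean Gaussian
#' noise band-limited to `[band_low, band_high]` (sharp spectral gating)
#' and scaled so the coefficient of variation of the AM equals `contrast`.
#' Mimics the beating produced by several static conspecifics; it has no
#' low-frequency power of its own, unlike motion-driven scenes.
#'
#' @param carrier_frequency carrier frequency in Hz.
#' @param band_low,band_high modulation band edges in Hz,
#'   `0 < band_low < band_high < carrier_frequency / 2`.
#' @param contrast target CV of the AM (e.g. 0.2).
#' @param config a [signal_config()].
#' @return A [time_series()] with attribute `"modulator"` holding
#'   \eqn{1 + m(t)} as a [time_series()].
#' @export
generate_narrowband_ram <- function(carrier_frequency, band_low, band_high,
                                    contrast, config) {
  stopifnot(inherits(config, "signal_config"))
  if (!(band_low > 0 && band_low < band_high &&
        band_high < carrier_frequency / 2))
    stop("generate_narrowband_ram: need 0 < band_low < band_high < carrier/2")
  if (config$sample_rate <= 2 * carrier_frequency)
    stop("generate_narrowband_ram: Nyquist violation")
  if (contrast < 0) stop("generate_narrowband_ram: contrast must be >= 0")
  n <- config$n_samples
  fs <- config$sample_rate
  tt <- (seq_len(n) - 1) / fs
  if (contrast == 0) {
    m <- rep(0, n)
  } else {
    m <- local_seed(config$seed, {
      w <- stats::rnorm(n)
      wf <- stats::fft(w)
      freqs <- (seq_len(n) - 1) * fs / n
      freqs <- pmin(freqs, fs - freqs)  # two-sided frequency magnitude
      keep <- freqs >= band_low & freqs <= band_high
      wf[!keep] <- 0
      Re(stats::fft(wf, inverse = TRUE)) / n
    })
    m <- m * contrast / stats::sd(m)
  }
  out <- time_series((1 + m) * sin(2 * pi * carrier_frequency * tt), fs)
  attr(out, "modulator") <- time_series(1 + m, fs)
  out
}
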