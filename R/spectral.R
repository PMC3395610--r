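# Welch spectral machinery shared by the PSD, cross-spectrum and coherence
# estimators: Hann-windowed, mean-removed, overlapping modified
# periodograms, one-sided density normalization (integral of the PSD over
# [0, Nyquist] equals the signal variance).

welch_segments <- function(n, nseg, overlap) {
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = step)
  if (length(starts) < 1L) stop("welch: record shorter than one segment")
  starts
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# Returns frequency grid plus averaged one-sided auto-spectra (xx, yy) and
# cross-spectrum (xy).  y may be NULL for a plain PSD.
welch_core <- function(x, y, fs, segment_seconds, overlap) {
  n <- length(x)
  nseg <- as.integer(round(segment_seconds * fs))
  if (nseg < 8L) stop("welch: segment too short")
  if (nseg > n) stop("welch: segment longer than the record")
  starts <- welch_segments(n, nseg, overlap)
  w <- hann_window(nseg)
  wnorm <- sum(w^2)
  nf <- nseg %/% 2 + 1L
  freqs <- (seq_len(nf) - 1) * fs / nseg
  sxx <- numeric(nf); syy <- numeric(nf); sxy <- complex(nf)
  for (s in starts) {
    idx <- s:(s + nseg - 1L)
    xs <- x[idx]; xs <- (xs - mean(xs)) * w
    X <- stats::fft(xs)[1:nf]
    sxx <- sxx + Re(X * Conj(X))
    if (!is.null(y)) {
      ys <- y[idx]; ys <- (ys - mean(ys)) * w
      Y <- stats::fft(ys)[1:nf]
      syy <- syy + Re(Y * Conj(Y))
      sxy <- sxy + Conj(X) * Y
    }
  }
  m <- length(starts)
  # one-sided density scaling; DC and Nyquist bins are not doubled
  scale <- 2 / (fs * wnorm) / m
  one_sided <- rep(1, nf)
  one_sided[1] <- 0.5
  if (nseg %% 2 == 0) one_sided[nf] <- 0.5
  list(frequencies = freqs,
       sxx = sxx * scale * one_sided,
       syy = if (is.null(y)) NULL else syy * scale * one_sided,
       sxy = if (is.null(y)) NULL else sxy * scale * one_sided,
       n_segments = m, segment_length = nseg / fs)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms (Hann window, mean removed per segment,
#' default 2 s segments with 50% overlap).  The estimate is a one-sided
#' density: its integral over frequency equals the signal variance
#' (Parseval), which the test-suite asserts on every fixture.
#'
#' @param series a [time_series()].
#' @param segment_seconds segment length in seconds (default 2).
#' @param overlap_fraction fractional overlap between segments (default 0.5).
#' @return An object of class `spectral_estimate`: `frequencies` (Hz),
#'   `power` (density per Hz), `segment_length`, `n_segments`.
#' @export
power_spectrum <- function(series, segment_seconds = 2,
                           overlap_fraction = 0.5) {
  stopifnot(inherits(series, "time_series"))
  wc <- welch_core(series$samples, NULL, series$sample_rate,
                   segment_seconds, overlap_fraction)
  structure(
    list(frequencies = wc$frequencies, power = wc$sxx,
         segment_length = wc$segment_length, n_segments = wc$n_segments),
    class = "spectral_estimate"
  )
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf(
    "<spectral_estimate: %d bins to %.4g Hz (df %.4g), %d segments of %g s>\n",
    length(x$frequencies), max(x$frequencies),
    x$frequencies[2] - x$frequencies[1], x$n_segments, x$segment_length))
  invisible(x)
}

#' @export
plot.spectral_estimate <- function(x, ..., log = "y", xlab = "frequency (Hz)",
                                   ylab = "PSD (1/Hz)", type = "l") {
  p <- x$power
  if (grepl("y", log)) p[p <= 0] <- NA
  graphics::plot(x$frequencies, p, log = log, xlab = xlab, ylab = ylab,
                 type = type, ...)
}

#' Integrated band power of a spectral estimate
#'
#' @param spectrum a `spectral_estimate`.
#' @param f_low,f_high band edges in Hz.
#' @return Power (variance units) in the band, by the trapezoidal rule.
#' @export
band_power <- function(spectrum, f_low, f_high) {
  keep <- spectrum$frequencies >= f_low & spectrum$frequencies <= f_high
  if (sum(keep) < 2L) stop("band_power: band contains fewer than 2 bins")
  trapz(spectrum$frequencies[keep], spectrum$power[keep])
}

#' Short-time amplitude spectrogram
#'
#' Hann-windowed short-time Fourier transform returning amplitude spectral
#' density; the amplitude track at a fish's EODf visualizes its
#' time-varying received amplitude (it follows E2).
#'
#' @param series a [time_series()].
#' @param window_seconds STFT window length in seconds.
#' @param step_seconds hop between windows in seconds.
#' @return List with `times` (s, window centers), `frequencies` (Hz) and
#'   `amplitude` (matrix, frequency x time), class `spectrogram`.
#' @export
spectrogram <- function(series, window_seconds = 0.5, step_seconds = 0.1) {
  stopifnot(inherits(series, "time_series"))
  if (window_seconds <= 0 || step_seconds <= 0)
    stop("spectrogram: window and step must be > 0")
  fs <- series$sample_rate
  x <- series$samples
  nwin <- as.integer(round(window_seconds * fs))
  step <- as.integer(round(step_seconds * fs))
  if (nwin > length(x)) stop("spectrogram: window longer than the record")
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- hann_window(nwin)
  nf <- nwin %/% 2 + 1L
  amp <- matrix(0, nf, length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + nwin - 1L)] * w
    amp[, j] <- Mod(stats::fft(seg)[1:nf])
  }
  structure(
    list(times = (starts - 1L + nwin / 2) / fs,
         frequencies = (seq_len(nf) - 1) * fs / nwin,
         amplitude = amp * 2 / sum(w),
         raw_magnitude = amp, window_ss = sum(w^2), n_window = nwin),
    class = "spectrogram"
  )
}

#' Amplitude track of a spectrogram at a given frequency
#'
#' Estimates the amplitude of the sinusoidal component near `frequency` in
#' each window by integrating windowed-DFT power over the peak cluster
#' (nearest bin plus `halfwidth` neighbours on each side), which removes
#' the scalloping loss a single off-grid bin readout would suffer.  For an
#' isolated tone of amplitude A the track equals A.
#'
#' @param spec a [spectrogram()].
#' @param frequency frequency of interest in Hz.
#' @param halfwidth number of neighbouring bins summed on each side
#'   (default 2).
#' @return A [time_series()] of the amplitude at that frequency (sampled at
#'   the spectrogram hop rate).
#' @export
spectrogram_track <- function(spec, frequency, halfwidth = 2) {
  stopifnot(inherits(spec, "spectrogram"))
  k <- which.min(abs(spec$frequencies - frequency))
  rows <- max(1L, k - halfwidth):min(nrow(spec$raw_magnitude), k + halfwidth)
  # Parseval for a windowed tone: sum |X_j|^2 over the one-sided peak
  # cluster ~= N * A^2 * sum(w^2) / 4
  p <- colSums(spec$raw_magnitude[rows, , drop = FALSE]^2)
  a <- sqrt(4 * p / (spec$n_window * spec$window_ss))
  dt <- if (length(spec$times) > 1L) diff(spec$times[1:2]) else 1
  time_series(a, 1 / dt, start_time = spec$times[1])
}

# mean-removed autocorrelation out to nlag, normalized to 1 at lag 0;
# computed via FFT (Wiener-Khinchin) with zero padding, so long lags on
# dense envelope grids stay cheap
acf_fft <- function(seg, nlag) {
  n <- length(seg)
  seg <- seg - mean(seg)
  m <- stats::nextn(n + nlag + 1L)
  F <- stats::fft(c(seg, numeric(m - n)))
  r <- Re(stats::fft(F * Conj(F), inverse = TRUE))[1:(nlag + 1L)]
  r / r[1]
}

#' Segment-averaged autocorrelation
#'
#' Mean-removed, variance-normalized autocorrelation, averaged over
#' consecutive segments (default 15 s) of the record; value 1 at lag 0.
#'
#' @param series a [time_series()].
#' @param max_lag maximum lag in seconds; must be below the segment length.
#' @param segment_seconds segment length in seconds (default 15; capped at
#'   the record length).
#' @return List with `lags` (s), `acf`, `n_segments`, class `acf_estimate`.
#' @export
autocorrelation <- function(series, max_lag, segment_seconds = 15) {
  stopifnot(inherits(series, "time_series"))
  fs <- series$sample_rate
  segment_seconds <- min(segment_seconds, ts_duration(series))
  if (max_lag >= segment_seconds)
    stop("autocorrelation: max_lag must be below the segment length")
  nseg <- as.integer(floor(segment_seconds * fs))
  nlag <- as.integer(round(max_lag * fs))
  x <- series$samples
  starts <- seq(1L, length(x) - nseg + 1L, by = nseg)
  acc <- numeric(nlag + 1L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    acc <- acc + acf_fft(seg, nlag)
  }
  structure(
    list(lags = (0:nlag) / fs, acf = acc / length(starts),
         n_segments = length(starts)),
    class = "acf_estimate"
  )
}

#' Fit an exponential correlation time to an autocorrelation
#'
#' Fits \eqn{a\,\exp(-\Delta t / \tau)} over the lags where the
#' autocorrelation exceeds 0.05 (least squares in correlation space, with
#' the amplitude profiled out analytically), recovering the
#' Ornstein-Uhlenbeck correlation time from, e.g., the autocorrelation of
#' the second envelope of a scene with a moving neighbour.  The amplitude
#' \eqn{a \le 1} is left free: measurement noise in the envelope adds an
#' uncorrelated component that inflates the lag-0 variance and rescales
#' the normalized autocorrelation without changing its decay time, so
#' pinning \eqn{a = 1} would bias \eqn{\tau} low.
#'
#' @param ac an `acf_estimate` from [autocorrelation()].
#' @param threshold only lags with `acf > threshold` enter the fit
#'   (default 0.05).
#' @return List with `tau` (s), `amplitude`, `residual` (RMS fit
#'   residual) and `ok` (`FALSE` when the autocorrelation does
#'   not decay below `exp(-1)` within the available lags, in which case
#'   `tau` is `NA`).
#' @export
fit_oup_correlation_time <- function(ac, threshold = 0.05) {
  stopifnot(inherits(ac, "acf_estimate"))
  if (min(ac$acf) > exp(-1))
    return(list(tau = NA_real_, amplitude = NA_real_, residual = NA_real_,
                ok = FALSE))
  keep <- ac$acf > threshold & ac$lags > 0
  if (sum(keep) < 3L)
    return(list(tau = NA_real_, amplitude = NA_real_, residual = NA_real_,
                ok = FALSE))
  lg <- ac$lags[keep]; r <- ac$acf[keep]
  # for fixed tau the optimal amplitude is a(tau) = <r,e>/<e,e>
  obj <- function(tau) {
    e <- exp(-lg / tau)
    a <- sum(r * e) / sum(e * e)
    sum((r - a * e)^2)
  }
  opt <- stats::optimize(obj, c(max(ac$lags[2] / 10, 1e-4),
                                10 * max(ac$lags)))
  tau <- opt$minimum
  e <- exp(-lg / tau)
  a <- sum(r * e) / sum(e * e)
  list(tau = tau, amplitude = a,
       residual = sqrt(opt$objective / length(lg)), ok = TRUE)
}

# Shared peak measurement on an arbitrary (frequency, value) curve.
measure_peak <- function(frequencies, values, center, reference_level,
                         search_halfwidth = 5) {
  near <- which(abs(frequencies - center) <= search_halfwidth)
  if (length(near) < 1L)
    stop("peak_metrics: no grid points within ", search_halfwidth,
         " Hz of center ", center)
  ipk <- near[which.max(values[near])]
  if ((ipk > 1 && values[ipk] < values[ipk - 1]) ||
      (ipk < length(values) && values[ipk] < values[ipk + 1]))
    stop("peak_metrics: no local maximum near center ", center)
  height <- values[ipk]
  if (reference_level >= height)
    stop("peak_metrics: reference level (", reference_level,
         ") is not below the peak height (", signif(height, 4), ")")
  # walk outwards to the flanking crossings of the reference level
  i <- ipk
  while (i > 1L && values[i] > reference_level) i <- i - 1L
  f_left <- if (values[i] > reference_level) frequencies[i] else {
    # linear interpolation between grid points i and i+1
    frequencies[i] + (reference_level - values[i]) /
      (values[i + 1L] - values[i]) * (frequencies[i + 1L] - frequencies[i])
  }
  j <- ipk
  nf <- length(values)
  while (j < nf && values[j] > reference_level) j <- j + 1L
  f_right <- if (values[j] > reference_level) frequencies[j] else {
    frequencies[j - 1L] + (values[j - 1L] - reference_level) /
      (values[j - 1L] - values[j]) * (frequencies[j] - frequencies[j - 1L])
  }
  width <- f_right - f_left
  if (width <= 0) stop("peak_metrics: degenerate width")
  structure(
    list(center = frequencies[ipk], height = height, width = width,
         resolution = height / width, reference_level = reference_level),
    class = "peak_metrics"
  )
}

#' @export
print.peak_metrics <- function(x, ...) {
  cat(sprintf(
    "<peak_metrics: center %.4g Hz, height %.4g, width %.4g Hz, resolution %.4g>\n",
    x$center, x$height, x$width, x$resolution))
  invisible(x)
}

#' Height, width and resolution of a spectral peak
#'
#' Finds the local maximum of the PSD within `search_halfwidth` of
#' `center`; the width is the distance between the two crossings of
#' `width_reference_level` flanking the peak (linear interpolation between
#' grid points), and the resolution is height/width.  Measuring the width
#' slightly above the noise floor makes it sensitive to peak broadening by
#' motion.
#'
#' @param spectrum a `spectral_estimate`.
#' @param center expected peak frequency in Hz.
#' @param width_reference_level density level at which the width is read.
#'   When `NULL`, it defaults to 10 times the local floor (median density
#'   within 50 Hz of the peak, excluding the central 5 Hz); pass an
#'   explicit common level when comparing widths across conditions.
#' @param search_halfwidth search window around `center` in Hz (default 5).
#' @return A `peak_metrics` object.
#' @export
peak_metrics <- function(spectrum, center, width_reference_level = NULL,
                         search_halfwidth = 5) {
  stopifnot(inherits(spectrum, "spectral_estimate"))
  if (is.null(width_reference_level))
    width_reference_level <- 10 * spectral_floor(spectrum, center)
  measure_peak(spectrum$frequencies, spectrum$power, center,
               width_reference_level, search_halfwidth)
}

#' Local noise-floor level around a spectral peak
#'
#' @param spectrum a `spectral_estimate`.
#' @param center peak frequency in Hz.
#' @param flank half-width of the flanking band (Hz, default 50).
#' @param exclude central half-width excluded as the peak itself (Hz).
#' @return Median density in the flanking band.
#' @export
spectral_floor <- function(spectrum, center, flank = 50, exclude = 5) {
  f <- spectrum$frequencies
  keep <- abs(f - center) <= flank & abs(f - center) > exclude & f > 0
  if (sum(keep) < 4L) stop("spectral_floor: flanking band too narrow")
  stats::median(spectrum$power[keep])
}

#' Period statistics of the first envelope
#'
#' Measures successive periods of the E1 waveform between upward crossings
#' of its local mean (sub-sample linear interpolation), histograms them on
#' 0.02 ms bins and reports the mode (center of the maximal bin; ties take
#' the lower bin) and the coefficient of variation.  Motion jitters the
#' beat period (CV grows with the neighbour's fluctuation scale), while a
#' larger neighbour amplitude locks the period to the beat.
#'
#' The crossing reference is the slow trend of E1 (zero-phase low-pass at
#' `detrend_cutoff`, well below any beat) rather than the global record
#' mean: the record mean of a beat envelope sits a quadratic-order offset
#' above its oscillation center, so global-mean crossings systematically
#' miss beats when the instantaneous beat amplitude dips below that
#' offset, which distorts period statistics as the neighbour amplitude
#' grows.  An additional `2 / detrend_cutoff` settling window is dropped
#' at each end after detrending.
#'
#' @param e1 a [time_series()] envelope.
#' @param binwidth histogram bin width in seconds (default 0.02 ms).
#' @param edge_seconds settling window excluded at each end.
#' @param detrend_cutoff low-pass cutoff (Hz) defining the local mean
#'   (default 20, the motion band's upper edge; keep below half the beat
#'   frequency).
#' @return An object of class `period_stats`: `periods` (s), `breaks`,
#'   `counts`, `mode` (s), `cv`.
#' @export
e1_periods <- function(e1, binwidth = 0.02e-3, edge_seconds = 0.05,
                       detrend_cutoff = 20) {
  stopifnot(inherits(e1, "time_series"))
  xt <- ts_trim_edges(e1, edge_seconds)
  if (diff(range(xt$samples)) < 1e-8 * max(abs(xt$samples), 1e-12))
    stop("e1_periods: no oscillatory component (fewer than 3 upward ",
         "mean-crossings)")
  trend <- lowpass_zerophase(xt$samples, detrend_cutoff, xt$sample_rate)
  # the near-DC trend filter rings over several of its own time constants;
  # drop a generous settling margin at both ends
  settle <- as.integer(round((2 / detrend_cutoff + 0.15) * xt$sample_rate))
  if (2L * settle + 16L > length(xt$samples))
    stop("e1_periods: record too short for detrending at ", detrend_cutoff,
         " Hz")
  x <- (xt$samples - trend)[(settle + 1L):(length(xt$samples) - settle)]
  up <- which(x[-length(x)] < 0 & x[-1] >= 0)
  if (length(up) < 3L) stop("e1_periods: fewer than 3 upward mean-crossings")
  frac <- -x[up] / (x[up + 1L] - x[up])
  tcross <- (up - 1 + frac) / xt$sample_rate
  periods <- diff(tcross)
  if (length(periods) < 2L) stop("e1_periods: fewer than 2 periods")
  breaks <- seq(0, (ceiling(max(periods) / binwidth) + 1) * binwidth,
                by = binwidth)
  counts <- as.numeric(table(cut(periods, breaks, right = FALSE)))
  imax <- which.max(counts)  # which.max takes the first (lower) bin on ties
  structure(
    list(periods = periods, breaks = breaks, counts = counts,
         mode = (breaks[imax] + breaks[imax + 1L]) / 2,
         cv = stats::sd(periods) / mean(periods)),
    class = "period_stats"
  )
}

#' @export
print.period_stats <- function(x, ...) {
  cat(sprintf("<period_stats: %d periods, mode %.4g ms, CV %.4g>\n",
              length(x$periods), 1000 * x$mode, x$cv))
  invisible(x)
}
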