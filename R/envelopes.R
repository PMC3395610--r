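#' Analytic signal via the Hilbert transform
#'
#' Returns \eqn{z(t) = x(t) + i\,\hat x(t)} where \eqn{\hat x} is the
#' Hilbert transform of `x`, computed by one-sided spectral weighting in
#' the FFT domain.  `Mod(analytic_signal(x))` is the instantaneous
#' amplitude of `x`.
#'
#' @param x numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 4L) stop("analytic_signal: input too short")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase 4th-order Butterworth low-pass.  Zero-phase (forward-backward)
# application preserves envelope timing, which matters for coherence
# analysis downstream.
lowpass_zerophase <- function(x, cutoff, fs, order = 4) {
  if (cutoff >= fs / 2) stop("lowpass_zerophase: cutoff must be below Nyquist")
  bf <- signal::butter(order, 2 * cutoff / fs)
  signal::filtfilt(bf, x)
}

#' Extract the first envelope E1
#'
#' The amplitude modulation of the raw composite signal: magnitude of the
#' analytic signal, low-pass filtered (zero-phase 4th-order Butterworth,
#' default cutoff 200 Hz) to remove the remnant spectral peak at the EOD
#' frequency.  E1 carries the beat frequencies (differences between EODfs).
#' The first and last 50 ms are filter-settling edges; statistics computed
#' elsewhere in the package exclude them.
#'
#' @param signal a [time_series()] (raw oscillatory signal).
#' @param lpf_cutoff low-pass cutoff in Hz (default 200).
#' @return A [time_series()] of the same length and rate as the input.
#' @export
extract_e1 <- function(signal, lpf_cutoff = 200) {
  stopifnot(inherits(signal, "time_series"))
  fs <- signal$sample_rate
  if (lpf_cutoff >= fs / 2) stop("extract_e1: lpf_cutoff must be below Nyquist")
  if (length(signal$samples) < 64L)
    stop("extract_e1: input too short for envelope filtering")
  env <- Mod(analytic_signal(signal$samples))
  out <- time_series(lowpass_zerophase(env, lpf_cutoff, fs), fs,
                     start_time = signal$start_time)
  attr(out, "edge_seconds") <- 0.05
  out
}

#' Extract the second envelope E2
#'
#' The slow envelope of E1, carrying motion-induced fluctuations and
#' secondary beats ("beats of beats").  E1 is processed in consecutive
#' windows (default 0.1 s): within each window the window mean is removed,
#' the magnitude of the analytic signal of the residual beat oscillation is
#' taken, and the mean is added back; the segments are assembled end to end
#' and the result is low-pass filtered (zero-phase Butterworth, default
#' 50 Hz) to suppress segment-boundary discontinuities.
#'
#' @param e1 a [time_series()], normally from [extract_e1()].
#' @param window window length in seconds (default 0.1).  Must exceed one
#'   period of the dominant oscillation of E1.
#' @param lpf_cutoff smoothing cutoff in Hz applied to the assembled E2.
#' @return A [time_series()] of the same length and rate as `e1`.
#' @export
extract_e2 <- function(e1, window = 0.1, lpf_cutoff = 50) {
  stopifnot(inherits(e1, "time_series"))
  fs <- e1$sample_rate
  n <- length(e1$samples)
  w <- as.integer(round(window * fs))
  if (w < 8L) stop("extract_e2: window too short")
  if (n < w) stop("extract_e2: series shorter than one window")
  x <- e1$samples
  # typical beat period from interior mean-crossings (skipped for an
  # essentially constant E1); each window must hold at least one beat
  k <- min(n %/% 4, as.integer(round(0.05 * fs)))
  xi <- x[(k + 1):(n - k)]
  xi <- xi - mean(xi)
  up <- which(xi[-length(xi)] < 0 & xi[-1] >= 0)
  if (length(up) >= 3L) {
    beat_period <- stats::median(diff(up)) / fs
    if (window < beat_period)
      stop("extract_e2: window (", window, " s) is shorter than one beat ",
           "period (", signif(beat_period, 3), " s)")
  }
  starts <- seq(1L, n, by = w)
  out <- numeric(n)
  for (s in starts) {
    e <- min(s + w - 1L, n)
    seg <- x[s:e]
    if (length(seg) < 8L) {        # degenerate tail: carry the mean
      out[s:e] <- mean(seg)
    } else {
      m <- mean(seg)
      out[s:e] <- Mod(analytic_signal(seg - m)) + m
    }
  }
  res <- time_series(lowpass_zerophase(out, lpf_cutoff, fs), fs,
                     start_time = e1$start_time)
  attr(res, "edge_seconds") <- 0.05
  res
}

#' Envelope by connecting successive oscillation peaks
#'
#' Direct (Hilbert-free) envelope: local maxima of the signal are joined by
#' monotone piecewise-cubic interpolation and resampled on the input grid.
#' Serves as an independent cross-check of [extract_e1()]/[extract_e2()].
#' A sample counts as a local maximum when strictly greater than both
#' neighbours; on plateaus the left-most sample is taken.
#'
#' @param signal a [time_series()] (oscillatory).
#' @return A [time_series()] on the same grid.
#' @export
extract_envelope_direct <- function(signal) {
  stopifnot(inherits(signal, "time_series"))
  x <- signal$samples
  pk <- local_maxima(x)
  if (length(pk) < 3L)
    stop("extract_envelope_direct: fewer than 3 local maxima")
  tt <- ts_times(signal)
  f <- stats::splinefun(tt[pk], x[pk], method = "monoH.FC")
  y <- f(tt)
  # hold the first/last peak value outside the peak span (no extrapolation)
  y[tt < tt[pk[1]]] <- x[pk[1]]
  y[tt > tt[pk[length(pk)]]] <- x[pk[length(pk)]]
  time_series(y, signal$sample_rate, start_time = signal$start_time)
}

# indices of strict local maxima; plateaus resolve to their left-most sample
# (a max is where the last nonzero slope was rising and the next is falling)
local_maxima <- function(x) {
  if (length(x) < 3L) return(integer(0))
  sgn <- sign(diff(x))
  nz <- which(sgn != 0)
  if (length(nz) < 2L) return(integer(0))
  s <- sgn[nz]
  turn <- which(s[-length(s)] > 0 & s[-1] < 0)
  nz[turn] + 1L
}

local_minima <- function(x) local_maxima(-x)

#' Instantaneous contrast of an amplitude modulation
#'
#' For each local maximum \eqn{H} of the envelope and the nearest following
#' local minimum \eqn{L}, the instantaneous contrast is
#' \eqn{(H - L)/(H + L)} (half-difference over average).  Mean and SD over
#' all such beat half-cycles characterize, respectively, the neighbour's
#' mean relative amplitude and its motion-induced variability.  Edge
#' windows are excluded before peak-picking.
#'
#' @param e1 a [time_series()] envelope (from [extract_e1()]).
#' @param edge_seconds settling window dropped from each end (default
#'   0.05 s).
#' @return An object of class `contrast_stats`: list with `mean_contrast`,
#'   `sd_contrast`, `n_half_cycles` and the per-cycle `contrasts`.
#' @export
instantaneous_contrast <- function(e1, edge_seconds = 0.05) {
  stopifnot(inherits(e1, "time_series"))
  x <- ts_trim_edges(e1, edge_seconds)$samples
  mx <- local_maxima(x)
  mn <- local_minima(x)
  if (length(mx) < 1L || length(mn) < 1L)
    stop("instantaneous_contrast: envelope has no max-min pairs")
  # pair each maximum with the nearest following minimum
  pos <- findInterval(mx, mn) + 1L
  ok <- pos <= length(mn)
  H <- x[mx[ok]]; L <- x[mn[pos[ok]]]
  ct <- (H - L) / (H + L)
  if (length(ct) < 1L)
    stop("instantaneous_contrast: no maximum followed by a minimum")
  structure(
    list(mean_contrast = mean(ct),
         sd_contrast = if (length(ct) > 1L) stats::sd(ct) else 0,
         n_half_cycles = length(ct), contrasts = ct),
    class = "contrast_stats"
  )
}

#' @export
print.contrast_stats <- function(x, ...) {
  cat(sprintf("<contrast_stats: mean %.4f, SD %.4f over %d half-cycles>\n",
              x$mean_contrast, x$sd_contrast, x$n_half_cycles))
  invisible(x)
}

#' First-order prediction of the two-fish amplitude modulation
#'
#' For a receiving fish (amplitude 1) and one neighbour with mean relative
#' amplitude \eqn{A_2 \ll 1} and fluctuation scale \eqn{\sigma_2}, Taylor
#' expansion of the composite-signal envelope gives the AM
#' \deqn{1 + A_2 (1 + \sigma_2 \xi(t)) \cos(2\pi \Delta f\, t),}
#' a combined sinusoidal + random amplitude modulation whose instantaneous
#' contrast has mean \eqn{\approx A_2} and SD \eqn{\approx A_2 \sigma_2}.
#'
#' @param sources list of two [eod_source()] (receiving fish first).
#' @return List with `mean_contrast`, `sd_contrast`, `beat_frequency` (Hz)
#'   and a human-readable `am_form` string.
#' @export
predict_am <- function(sources) {
  if (length(sources) != 2L)
    stop("predict_am: the first-order theory applies to the two-fish case")
  s2 <- sources[[2]]
  a2 <- s2$mean_amplitude
  if (a2 >= 0.5)
    warning("predict_am: A2 = ", a2,
            " is large; the first-order (Taylor) approximation degrades")
  df <- abs(sources[[1]]$eod_frequency - s2$eod_frequency)
  list(
    mean_contrast = a2,
    sd_contrast = a2 * s2$amplitude_sd,
    beat_frequency = df,
    am_form = sprintf("1 + %.3g (1 + %.3g xi(t)) cos(2 pi %.4g t)",
                      a2, s2$amplitude_sd, df)
  )
}

#' Extract both envelopes at once
#'
#' @param signal raw [time_series()].
#' @param lpf_cutoff E1 low-pass cutoff in Hz.
#' @param window E2 window in seconds.
#' @return List with elements `e1` and `e2`.
#' @export
extract_envelopes <- function(signal, lpf_cutoff = 200, window = 0.1) {
  e1 <- extract_e1(signal, lpf_cutoff)
  list(e1 = e1, e2 = extract_e2(e1, window))
}
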