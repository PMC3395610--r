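# Coherence and mutual-information readouts quantifying how well P-unit
# responses encode the first (beat) and second (motion) envelopes.

check_same_grid <- function(x, y) {
  if (abs(x$sample_rate - y$sample_rate) > 1e-6 * x$sample_rate)
    stop("mismatched sample rates (", x$sample_rate, " vs ", y$sample_rate,
         " Hz); resample onto a common grid first")
  if (length(x$samples) != length(y$samples))
    stop("mismatched lengths (", length(x$samples), " vs ",
         length(y$samples), " samples)")
}

#' Welch cross-spectral density
#'
#' Averaged cross-periodogram between two series on the same grid (Hann
#' window, per-segment mean removal, one-sided density normalization
#' matching [power_spectrum()]).  With `y = x` it reduces to the
#' auto-spectrum.
#'
#' @param x,y [time_series()] objects with equal rates and durations
#'   (convert spike trains with [spikes_to_rate()] and decimate envelopes
#'   with [ts_decimate()] first).
#' @param segment_seconds,overlap_fraction Welch settings (defaults 2 s,
#'   50%).
#' @return An object of class `cross_spectrum`: `frequencies` (Hz),
#'   complex `cross` density, `n_segments`, `segment_length`.
#' @export
cross_spectrum <- function(x, y, segment_seconds = 2,
                           overlap_fraction = 0.5) {
  stopifnot(inherits(x, "time_series"), inherits(y, "time_series"))
  check_same_grid(x, y)
  wc <- welch_core(x$samples, y$samples, x$sample_rate, segment_seconds,
                   overlap_fraction)
  structure(
    list(frequencies = wc$frequencies, cross = wc$sxy,
         n_segments = wc$n_segments, segment_length = wc$segment_length),
    class = "cross_spectrum"
  )
}

#' Magnitude-squared coherence
#'
#' \eqn{C(f) = |S_{xy}(f)|^2 / (S_{xx}(f) S_{yy}(f))}: a frequency-resolved
#' squared correlation coefficient between 0 (no linear relation) and 1
#' (perfect linear relation).  The estimate is biased upward by roughly
#' `1/n_segments`; at least 8 averaging segments are required (2 would
#' already be degenerate, and a single segment gives identically 1).
#'
#' @param x,y [time_series()] on a common grid.
#' @param segment_seconds,overlap_fraction Welch settings.
#' @param min_segments minimum acceptable number of segments (default 8).
#' @return An object of class `coherence_estimate`: `frequencies`,
#'   `coherence` in `[0, 1]`, `n_segments`.
#' @export
coherence <- function(x, y, segment_seconds = 2, overlap_fraction = 0.5,
                      min_segments = 8) {
  stopifnot(inherits(x, "time_series"), inherits(y, "time_series"))
  check_same_grid(x, y)
  wc <- welch_core(x$samples, y$samples, x$sample_rate, segment_seconds,
                   overlap_fraction)
  if (wc$n_segments < 2L)
    stop("coherence: a single-segment estimate is identically 1; ",
         "use shorter segments or a longer record")
  if (wc$n_segments < min_segments)
    warning("coherence: only ", wc$n_segments,
            " segments; the estimate has bias ~1/n_segments")
  co <- Mod(wc$sxy)^2 / (wc$sxx * wc$syy)
  co[!is.finite(co)] <- 0
  co <- pmin(pmax(co, 0), 1)
  structure(
    list(frequencies = wc$frequencies, coherence = co,
         n_segments = wc$n_segments),
    class = "coherence_estimate"
  )
}

#' @export
print.coherence_estimate <- function(x, ...) {
  cat(sprintf(
    "<coherence_estimate: %d bins to %.4g Hz, %d segments, max %.3f at %.4g Hz>\n",
    length(x$frequencies), max(x$frequencies), x$n_segments,
    max(x$coherence), x$frequencies[which.max(x$coherence)]))
  invisible(x)
}

#' @export
plot.coherence_estimate <- function(x, ..., xlab = "frequency (Hz)",
                                    ylab = "coherence", type = "l",
                                    ylim = c(0, 1)) {
  graphics::plot(x$frequencies, x$coherence, xlab = xlab, ylab = ylab,
                 type = type, ylim = ylim, ...)
}

#' Peak metrics of a coherence function
#'
#' As [peak_metrics()] but on coherence values; the default width reference
#' 0.15 sits slightly above the typical estimation floor, so widths grow as
#' motion blurs the beat peak.
#'
#' @param coh a `coherence_estimate`.
#' @param center expected peak frequency in Hz.
#' @param reference_level coherence level at which to read the width.
#' @param search_halfwidth search window around `center` in Hz.
#' @return A `peak_metrics` object.
#' @export
coherence_peak_metrics <- function(coh, center, reference_level = 0.15,
                                   search_halfwidth = 5) {
  stopifnot(inherits(coh, "coherence_estimate"))
  measure_peak(coh$frequencies, coh$coherence, center, reference_level,
               search_halfwidth)
}

#' Mean coherence over a band
#'
#' @param coh a `coherence_estimate`.
#' @param f_low,f_high band edges in Hz.
#' @param exclude_dc drop the 0 Hz bin (default `TRUE`).
#' @return Mean coherence over the band's grid points.
#' @export
band_coherence <- function(coh, f_low, f_high, exclude_dc = TRUE) {
  keep <- coh$frequencies >= f_low & coh$frequencies <= f_high
  if (exclude_dc) keep <- keep & coh$frequencies > 0
  if (!any(keep)) stop("band_coherence: empty band")
  mean(coh$coherence[keep])
}

#' Gaussian-channel mutual-information rate from coherence
#'
#' Lower-bound information rate
#' \deqn{R_{MI} = -\int_{f_l}^{f_u} \log_2(1 - C(f))\, df}
#' (bits/s), trapezoidal on the native frequency grid.  The DC bin is
#' excluded (the mean-rate offset carries no envelope information) and the
#' coherence is capped at \eqn{1 - 10^{-6}} before the logarithm.
#'
#' @param coh a `coherence_estimate`.
#' @param f_low,f_high integration band in Hz (e.g. 0-20 Hz for the
#'   motion band).
#' @return An object of class `mi_estimate`: `rate` (bits/s), `band`.
#' @export
mutual_info_rate <- function(coh, f_low, f_high) {
  stopifnot(inherits(coh, "coherence_estimate"))
  f <- coh$frequencies
  keep <- f >= f_low & f <= f_high & f > 0
  if (sum(keep) < 2L) stop("mutual_info_rate: band contains fewer than 2 bins")
  cc <- pmin(coh$coherence[keep], 1 - 1e-6)
  structure(
    list(rate = max(0, -trapz(f[keep], log2(1 - cc))),
         band = c(f_low, f_high)),
    class = "mi_estimate"
  )
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate: %.3g bits/s over %g-%g Hz>\n",
              x$rate, x$band[1], x$band[2]))
  invisible(x)
}

#' Coherence between an envelope and a spike train
#'
#' Convenience wrapper: bins the spike train on a grid (default 0.5 ms)
#' whose rate divides the envelope's sample rate, decimates the
#' (band-limited) envelope onto that grid, and computes the coherence.
#'
#' @param envelope a [time_series()] (E1, E2 or a modulator).
#' @param spike_train a `spike_train`.
#' @param segment_seconds,overlap_fraction Welch settings.
#' @param bin spike binning in seconds.
#' @return A `coherence_estimate`.
#' @export
envelope_response_coherence <- function(envelope, spike_train,
                                        segment_seconds = 2,
                                        overlap_fraction = 0.5,
                                        bin = 5e-4) {
  r <- spikes_to_rate(spike_train, bin)
  e <- ts_decimate(envelope, 1 / bin)
  n <- min(length(e$samples), length(r$samples))
  e <- time_series(e$samples[seq_len(n)], e$sample_rate)
  r <- time_series(r$samples[seq_len(n)], r$sample_rate)
  coherence(e, r, segment_seconds, overlap_fraction)
}
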