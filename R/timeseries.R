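#' Uniformly sampled time series
#'
#' Lightweight container for a uniformly sampled, real-valued signal.  All
#' signals in the package (raw composite EOD signals, envelopes, firing
#' rates) are carried in this form.
#'
#' @param samples numeric vector of samples; must be finite.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param start_time time of the first sample in seconds.
#' @return An object of class `time_series`.
#' @export
time_series <- function(samples, sample_rate, start_time = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("time_series: 'samples' is empty")
  if (!all(is.finite(samples))) stop("time_series: samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("time_series: 'sample_rate' must be a positive scalar (Hz)")
  structure(
    list(samples = samples, sample_rate = sample_rate, start_time = start_time),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series: %d samples @ %g Hz, %.6g s, range [%.4g, %.4g]>\n",
              length(x$samples), x$sample_rate, ts_duration(x),
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
plot.time_series <- function(x, ..., xlab = "time (s)", ylab = "value",
                             type = "l") {
  graphics::plot(ts_times(x), x$samples, type = type,
                 xlab = xlab, ylab = ylab, ...)
}

#' @export
length.time_series <- function(x) length(x$samples)

#' Sample times of a time series
#' @param x a [time_series()].
#' @return Numeric vector of sample times in seconds.
#' @export
ts_times <- function(x) {
  x$start_time + (seq_along(x$samples) - 1) / x$sample_rate
}

#' Duration of a time series in seconds
#' @param x a [time_series()].
#' @export
ts_duration <- function(x) length(x$samples) / x$sample_rate

#' Clip a time series to a time window
#'
#' @param x a [time_series()].
#' @param from,to window bounds in seconds (relative to the series start).
#' @return The clipped `time_series`.
#' @export
ts_window <- function(x, from = 0, to = ts_duration(x)) {
  tt <- ts_times(x) - x$start_time
  keep <- tt >= from & tt < to
  if (!any(keep)) stop("ts_window: empty selection")
  time_series(x$samples[keep], x$sample_rate,
              start_time = x$start_time + from)
}

#' Drop filter-settling edges
#'
#' Removes the first and last `seconds` of a series.  Envelope statistics in
#' the package exclude these settling windows by default.
#'
#' @param x a [time_series()].
#' @param seconds edge duration to drop from each end (default 0.05 s).
#' @export
ts_trim_edges <- function(x, seconds = 0.05) {
  n <- length(x$samples)
  k <- round(seconds * x$sample_rate)
  if (2 * k >= n) stop("ts_trim_edges: series shorter than twice the edge window")
  time_series(x$samples[(k + 1):(n - k)], x$sample_rate,
              start_time = x$start_time + k / x$sample_rate)
}

#' Resample a band-limited series onto a coarser grid by decimation
#'
#' Picks every k-th sample; only valid when the series has no power above
#' half the target rate (e.g. envelopes after low-pass filtering).
#'
#' @param x a [time_series()].
#' @param rate target sample rate in Hz; must divide `x$sample_rate`.
#' @export
ts_decimate <- function(x, rate) {
  k <- x$sample_rate / rate
  if (abs(k - round(k)) > 1e-8)
    stop("ts_decimate: target rate must divide the sample rate")
  k <- as.integer(round(k))
  time_series(x$samples[seq(1L, length(x$samples), by = k)], rate,
              start_time = x$start_time)
}

#' Write a time series to two-column delimited text
#'
#' @param x a [time_series()].
#' @param path output file; columns are time (s) and value, tab-separated.
#' @export
write_timeseries <- function(x, path) {
  utils::write.table(
    data.frame(time = ts_times(x), value = x$samples),
    path, sep = "\t", row.names = FALSE, col.names = TRUE, quote = FALSE
  )
  invisible(path)
}

#' Read a time series from two-column delimited text
#'
#' The sample rate is inferred from the (required uniform) time column.
#'
#' @param path file written by [write_timeseries()] or any two-column
#'   time/value text file with a header.
#' @export
read_timeseries <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (ncol(d) < 2L) stop("read_timeseries: expected two columns (time, value)")
  dt <- diff(d[[1]])
  if (length(dt) < 1L || any(abs(dt - dt[1]) > 1e-6 * dt[1]))
    stop("read_timeseries: time column is not uniformly sampled")
  time_series(d[[2]], sample_rate = 1 / dt[1], start_time = d[[1]][1])
}
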