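#' Construct a uniformly sampled signal
#'
#' A `osa_series` is the basic substrate of the pipeline: an ordered vector of
#' real samples together with its sampling rate in Hz and a channel label.
#' All estimators (DFA, ApEn, LLE, T90) and all windowing operations act on
#' this type.
#'
#' @param values Numeric vector of samples (at least one, all finite unless
#'   `allow_na` is set).
#' @param rate Sampling rate in samples per second (Hz); must be positive.
#' @param label Channel name, e.g. `"Flow"`.
#' @return An object of class `osa_series` with fields `values`, `rate`,
#'   `label`.
#' @examples
#' s <- series(sin(2 * pi * seq(0, 60, by = 0.1) / 4), rate = 10, label = "Flow")
#' series_duration(s)
#' @export
series <- function(values, rate, label = "signal") {
  if (!is.numeric(values) || length(values) < 1) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(values = as.numeric(values), rate = as.numeric(rate),
         label = as.character(label)[1]),
    class = "osa_series"
  )
}

#' @export
print.osa_series <- function(x, ...) {
  cat(sprintf("<osa_series> '%s': %d samples @ %g Hz (%.1f s)\n",
              x$label, length(x$values), x$rate, series_duration(x)))
  invisible(x)
}

#' Duration of a series in seconds
#'
#' Exactly `length(values) / rate`.
#'
#' @param s An `osa_series`.
#' @return Duration in seconds.
#' @export
series_duration <- function(s) {
  stopifnot(inherits(s, "osa_series"))
  length(s$values) / s$rate
}

#' Construct an overnight sleep recording
#'
#' Bundles the three physiological channels of one subject-night: nasal
#' cannula airflow, thoracic belt movement and pulse-oximetry SpO2. The three
#' channels must cover the same time span to within one sample period of the
#' coarsest channel, and SpO2 values must lie in [0, 100].
#'
#' @param flow `osa_series`, nasal cannula airflow (typically 200 Hz).
#' @param thoracic `osa_series`, thoracic belt movement (typically 10 Hz).
#' @param spo2 `osa_series`, oxygen saturation in percent (typically 1 Hz).
#' @param start_offset Seconds between recorder start and lights-off; kept as
#'   metadata (analysis windows are expressed relative to recording start).
#' @return An object of class `sleep_recording`.
#' @export
sleep_recording <- function(flow, thoracic, spo2, start_offset = 0) {
  for (ch in list(flow, thoracic, spo2)) {
    stopifnot(inherits(ch, "osa_series"))
  }
  if (any(spo2$values < -1e-9 | spo2$values > 100 + 1e-9, na.rm = TRUE)) {
    stop("SpO2 values must lie in [0, 100]", call. = FALSE)
  }
  durs <- c(series_duration(flow), series_duration(thoracic), series_duration(spo2))
  tol <- 1 / min(flow$rate, thoracic$rate, spo2$rate)
  if (max(durs) - min(durs) > tol + 1e-9) {
    stop(sprintf(
      "channels must cover the same time span (durations %.2f / %.2f / %.2f s)",
      durs[1], durs[2], durs[3]), call. = FALSE)
  }
  structure(
    list(flow = flow, thoracic = thoracic, spo2 = spo2,
         start_offset = as.numeric(start_offset),
         total_duration = max(durs)),
    class = "sleep_recording"
  )
}

#' @export
print.sleep_recording <- function(x, ...) {
  cat(sprintf("<sleep_recording> %.1f min\n", x$total_duration / 60))
  for (ch in c("flow", "thoracic", "spo2")) {
    s <- x[[ch]]
    cat(sprintf("  %-8s '%s': %d samples @ %g Hz\n",
                ch, s$label, length(s$values), s$rate))
  }
  invisible(x)
}

#' Extract a contiguous analysis window
#'
#' Windows are half-open intervals `[start, start + duration)` in seconds;
#' sample indexing is 0-based, so the slice begins at sample index
#' `floor(start * rate)` and has `round(duration * rate)` samples. This
#' convention makes nested extraction compose exactly:
#' `extract_window(extract_window(s, a, d1), b, d2)` equals
#' `extract_window(s, a + b, d2)`.
#'
#' @param s An `osa_series`.
#' @param start Window start in seconds from the beginning of `s` (>= 0).
#' @param duration Window length in seconds.
#' @return An `osa_series` with the same rate and label.
#' @export
extract_window <- function(s, start, duration) {
  stopifnot(inherits(s, "osa_series"))
  if (start < 0) stop("`start` must be >= 0", call. = FALSE)
  avail <- series_duration(s)
  if (start + duration > avail + 1e-9) {
    stop(sprintf(
      "window [%g, %g) s exceeds signal extent: %g s available",
      start, start + duration, avail), call. = FALSE)
  }
  i0 <- floor(start * s$rate)             # 0-based first sample
  n <- round(duration * s$rate)
  series(s$values[(i0 + 1):(i0 + n)], rate = s$rate, label = s$label)
}

#' Decimate a series by keeping every k-th value
#'
#' Plain value-keeping: samples at 0-based indices 0, k, 2k, ... are retained
#' and the rate is divided by `k`. No anti-alias filtering is applied -- the
#' operation is deliberately the literal "keep every fourth value" reduction
#' that defines the `f2` (quarter-rate flow) feature family, not a filtered
#' resampling.
#'
#' @param s An `osa_series`.
#' @param k Positive integer stride.
#' @return An `osa_series` at rate `rate / k`.
#' @export
decimate_keep_kth <- function(s, k) {
  stopifnot(inherits(s, "osa_series"))
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  idx <- seq.int(1L, length(s$values), by = k)
  series(s$values[idx], rate = s$rate / k, label = s$label)
}

#' Resample a series by block averaging
#'
#' Reduces a series to `target_rate` by taking the mean within consecutive
#' blocks of `rate / target_rate` samples (the ratio must be a positive
#' integer). Used to bring high-rate respiratory channels to the 1 Hz
#' resolution at which approximate entropy is computed, and to the working
#' rate of the Lyapunov estimator. Unlike [decimate_keep_kth()], block
#' averaging suppresses within-block noise.
#'
#' @param s An `osa_series`.
#' @param target_rate Target rate in Hz; `s$rate / target_rate` must be a
#'   whole number.
#' @return An `osa_series` at `target_rate`.
#' @export
resample_mean <- function(s, target_rate) {
  stopifnot(inherits(s, "osa_series"))
  if (target_rate > s$rate + 1e-12) {
    stop("`target_rate` must not exceed the native rate", call. = FALSE)
  }
  k <- s$rate / target_rate
  if (abs(k - round(k)) > 1e-9) {
    stop("rate / target_rate must be a whole number", call. = FALSE)
  }
  k <- as.integer(round(k))
  if (k == 1L) return(s)
  n_full <- (length(s$values) %/% k) * k
  m <- matrix(s$values[seq_len(n_full)], nrow = k)
  series(colMeans(m), rate = target_rate, label = s$label)
}
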