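#' EMG preprocessing
#'
#' The envelope chain: least-squares linear detrend, 20-500 Hz band-pass,
#' 60 Hz mains notch, 6-sample windowed-RMS rectification, 4th-order 5 Hz
#' low-pass, and MVC normalization.  All filters are Butterworth designs
#' applied forward-backward (zero phase) so activation-onset timing is not
#' biased.  Every stage records itself in a `provenance` attribute.
#'
#' @name emg-preprocessing
NULL

add_provenance <- function(x, step) {
  attr(x, "provenance") <- c(attr(x, "provenance"), step)
  x
}

#' Remove a least-squares linear trend (offset + slope)
#'
#' Removing the full linear trend is strictly more general than plain
#' mean subtraction and reduces to it for trendless signals.
#'
#' @param series [sensor_channel].
#' @return detrended [sensor_channel]; output mean is 0 to numerical
#'   precision.
#' @export
detrend_signal <- function(series) {
  x <- series$samples
  if (length(x) < 2) stop_invalid("detrend needs at least 2 samples")
  t <- seq_along(x)
  fit <- stats::lm.fit(cbind(1, t), x)
  out <- series
  out$samples <- unname(fit$residuals)
  add_provenance(out, "detrend(linear)")
}

apply_filtfilt <- function(series, filt, step) {
  out <- series
  out$samples <- as.numeric(signal::filtfilt(filt, series$samples))
  add_provenance(out, step)
}

#' Band-pass filter (Butterworth, zero phase)
#'
#' @param series [sensor_channel].
#' @param low,high band edges in Hz (defaults 20 and 500, the EMG analysis
#'   band).  If `high` reaches the Nyquist frequency it is clamped to
#'   `0.45 * fs` with a warning.
#' @param order filter order (applied twice by the zero-phase pass).
#' @return filtered [sensor_channel].
#' @export
bandpass_filter <- function(series, low = 20, high = 500, order = 4) {
  fs <- series$fs
  if (low <= 0 || high <= low) {
    stop_invalid("band edges must satisfy 0 < low < high (got %g, %g)", low, high)
  }
  if (high >= fs / 2) {
    warning(sprintf("band-pass upper edge %g Hz >= Nyquist (fs = %g); clamped to %g Hz",
                    high, fs, 0.45 * fs))
    high <- 0.45 * fs
    if (high <= low) stop_invalid("fs = %g Hz too low for a %g Hz lower edge", fs, low)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  apply_filtfilt(series, bf, sprintf("bandpass(%g-%g Hz, order %d)", low, high, order))
}

#' Mains notch filter
#'
#' Second-order Butterworth band-stop of width `f0 / Q` centred on `f0`,
#' zero phase.
#'
#' @param series [sensor_channel].
#' @param f0 notch frequency in Hz (60 Hz mains by default).
#' @param Q quality factor; the stop band is `f0 +- f0 / (2 Q)`.
#' @return filtered [sensor_channel].
#' @export
notch_filter <- function(series, f0 = 60, Q = 30) {
  fs <- series$fs
  if (f0 >= fs / 2) stop_invalid("notch frequency %g Hz >= Nyquist (fs = %g)", f0, fs)
  bw <- f0 / Q
  bf <- signal::butter(2, c(f0 - bw / 2, f0 + bw / 2) / (fs / 2), type = "stop")
  apply_filtfilt(series, bf, sprintf("notch(%g Hz, Q=%g)", f0, Q))
}

#' Windowed RMS rectification
#'
#' Centred moving root-mean-square with edge truncation (the window
#' shrinks at the boundaries).  With the default 6-sample window at
#' 2000 Hz this is a 3 ms rectifier.
#'
#' @param series [sensor_channel].
#' @param window window length in samples.
#' @return non-negative [sensor_channel].
#' @export
rms_envelope <- function(series, window = 6) {
  x <- series$samples
  n <- length(x)
  if (window < 1 || window > n) {
    stop_invalid("RMS window must lie in [1, %d], got %g", n, window)
  }
  sq <- c(0, cumsum(x^2))
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  out <- series
  out$samples <- sqrt((sq[hi + 1] - sq[lo]) / (hi - lo + 1))
  add_provenance(out, sprintf("rms(window %d)", window))
}

#' Low-pass envelope smoothing
#'
#' 4th-order Butterworth low-pass (zero phase), then clipped at zero to
#' preserve the envelope's non-negativity contract.
#'
#' @param series [sensor_channel].
#' @param cutoff cutoff frequency in Hz.
#' @param order filter order.
#' @return smoothed non-negative [sensor_channel].
#' @export
lowpass_envelope <- function(series, cutoff = 5, order = 4) {
  fs <- series$fs
  if (cutoff >= fs / 2) stop_invalid("cutoff %g Hz >= Nyquist (fs = %g)", cutoff, fs)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  out <- apply_filtfilt(series, bf,
                        sprintf("lowpass(%g Hz, order %d)", cutoff, order))
  out$samples <- pmax(out$samples, 0)
  out
}

#' Normalize an envelope by the MVC reference
#'
#' @param envelope [sensor_channel] envelope (uV).
#' @param mvc_value positive MVC amplitude in the same units.
#' @return `emg_envelope` object: samples as fraction of MVC, with `fs` and
#'   `provenance`.
#' @export
normalize_mvc <- function(envelope, mvc_value) {
  if (!is.numeric(mvc_value) || length(mvc_value) != 1 || !is.finite(mvc_value) ||
      mvc_value <= 0) {
    stop_invalid("mvc_value must be a positive number")
  }
  out <- envelope
  out$samples <- envelope$samples / mvc_value
  out <- add_provenance(out, sprintf("mvc_normalize(%g)", mvc_value))
  class(out) <- c("emg_envelope", class(out))
  out
}

#' Full EMG preprocessing chain
#'
#' detrend -> band-pass -> notch -> windowed RMS -> low-pass -> MVC
#' normalization, each stage with its default parameters unless overridden.
#'
#' @param raw [sensor_channel] of raw EMG.
#' @param mvc_value positive MVC reference (uV envelope units).
#' @param low,high band-pass edges in Hz.
#' @param notch_f0,notch_Q notch parameters.
#' @param rms_window RMS window in samples.
#' @param lp_cutoff,lp_order envelope low-pass parameters.
#' @param keep_filtered if `TRUE`, the detrended/band-passed/notched signal
#'   (the input to rectification) is attached as attribute `"filtered"`;
#'   the linear-variability and spectral features are computed from it.
#' @return `emg_envelope` (MVC-normalized, non-negative).
#' @export
preprocess_emg <- function(raw, mvc_value, low = 20, high = 500,
                           notch_f0 = 60, notch_Q = 30, rms_window = 6,
                           lp_cutoff = 5, lp_order = 4,
                           keep_filtered = FALSE) {
  x <- detrend_signal(raw)
  x <- bandpass_filter(x, low, high)
  x <- notch_filter(x, notch_f0, notch_Q)
  filtered <- x
  x <- rms_envelope(x, rms_window)
  x <- lowpass_envelope(x, lp_cutoff, lp_order)
  env <- normalize_mvc(x, mvc_value)
  if (keep_filtered) attr(env, "filtered") <- filtered
  env
}
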