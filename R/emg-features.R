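#' Muscle activation threshold from a resting baseline
#'
#' Threshold = baseline mean + 5 x baseline SD (sample SD, n - 1
#' denominator), computed on the preprocessed baseline envelope.
#'
#' @param baseline numeric vector, [sensor_channel] or `emg_envelope` of the
#'   resting segment (envelope units).
#' @return list with `value`, `baseline_mean`, `baseline_sd`.
#' @export
compute_threshold <- function(baseline) {
  x <- if (is.list(baseline)) baseline$samples else baseline
  if (length(x) < 2) stop_invalid("baseline must have at least 2 samples")
  m <- mean(x)
  s <- sd(x)
  list(value = m + 5 * s, baseline_mean = m, baseline_sd = s)
}

#' Detect muscle activity onset / cessation
#'
#' Onset is the first envelope sample above threshold, cessation the last;
#' total activation time is their difference in seconds.  A recording that
#' never crosses the threshold has `total_time = 0` and `NA` onset and
#' cessation (absence, not an error).
#'
#' @param envelope `emg_envelope` or [sensor_channel].
#' @param threshold threshold value (same units as the envelope) or the list
#'   returned by [compute_threshold()].
#' @param mode `"span"` (first onset to last cessation, default) or
#'   `"episodes"` (sum of above-threshold episode durations).
#' @return list with `onset_time`, `cessation_time`, `total_time` (seconds).
#' @export
detect_activity <- function(envelope, threshold, mode = c("span", "episodes")) {
  mode <- match.arg(mode)
  thr <- if (is.list(threshold)) threshold$value else threshold
  x <- envelope$samples
  fs <- envelope$fs
  above <- which(x > thr)
  if (length(above) == 0) {
    return(list(onset_time = NA_real_, cessation_time = NA_real_, total_time = 0))
  }
  onset <- (above[1] - 1) / fs
  cessation <- (above[length(above)] - 1) / fs
  total <- if (mode == "span") {
    cessation - onset
  } else {
    r <- rle(x > thr)
    sum(r$lengths[r$values]) / fs
  }
  list(onset_time = onset, cessation_time = cessation, total_time = total)
}

#' Cumulative muscular workload (CMW)
#'
#' Time integral of the MVC-normalized envelope over the whole task
#' (trapezoidal rule), in (fraction of MVC) x seconds.
#'
#' @param envelope `emg_envelope` (MVC-normalized).  A non-normalized input
#'   triggers a warning, not an error.
#' @return non-negative scalar.
#' @export
cumulative_muscular_workload <- function(envelope) {
  prov <- attr(envelope, "provenance")
  if (!is.null(prov) && !any(grepl("mvc_normalize", prov))) {
    warning("envelope provenance does not include MVC normalization")
  }
  x <- envelope$samples
  if (length(x) < 2) return(0)
  t <- (seq_along(x) - 1) / envelope$fs
  pracma::trapz(t, x)
}

#' Average muscular work per second (AWS)
#'
#' CMW divided by performance time.  Performance time defaults to the full
#' trial duration (the task completion time), a quantity distinct from the
#' muscle activation time.
#'
#' @param cmw cumulative muscular workload.
#' @param performance_time positive duration in seconds.
#' @return scalar.
#' @export
average_work_per_second <- function(cmw, performance_time) {
  if (!is.finite(performance_time) || performance_time <= 0) {
    stop_invalid("performance_time must be positive, got %g", performance_time)
  }
  cmw / performance_time
}

#' Whole-recording RMS
#' @param signal numeric vector or [sensor_channel].
#' @return sqrt(mean of squares).
#' @export
emg_rms <- function(signal) {
  x <- if (is.list(signal)) signal$samples else signal
  if (length(x) < 1) stop_invalid("empty signal")
  sqrt(mean(x^2))
}

#' Signal range (max - min)
#' @param signal numeric vector or [sensor_channel].
#' @return non-negative scalar.
#' @export
signal_range <- function(signal) {
  x <- if (is.list(signal)) signal$samples else signal
  if (length(x) < 1) stop_invalid("empty signal")
  max(x) - min(x)
}

#' Dominant frequency via zero-padded FFT power spectrum
#'
#' The signal is linearly detrended, zero-padded to the next power of two,
#' Fourier transformed, and the squared modulus taken as the raw power
#' spectral density.  The dominant frequency is the positive-frequency
#' argmax (DC excluded; ties broken toward the lowest frequency).
#'
#' @param signal numeric vector or [sensor_channel].
#' @param fs sampling rate in Hz (taken from the channel if omitted).
#' @return frequency in Hz, or `NA` for an (all-zero) signal with no
#'   spectral content.
#' @export
dominant_frequency <- function(signal, fs = NULL) {
  if (is.list(signal)) {
    if (is.null(fs)) fs <- signal$fs
    x <- signal$samples
  } else {
    x <- signal
  }
  if (is.null(fs)) stop_invalid("fs required when signal is a bare vector")
  n <- length(x)
  if (n < 16) stop_invalid("dominant_frequency needs at least 16 samples")
  t <- seq_len(n)
  x <- unname(stats::lm.fit(cbind(1, t), x)$residuals)
  nfft <- 2^ceiling(log2(n))
  spec <- Mod(fft(c(x, numeric(nfft - n))))^2
  # positive frequencies only, DC excluded
  idx <- 2:(nfft %/% 2 + 1)
  psd <- spec[idx]
  if (max(psd) <= .Machine$double.eps * n) return(NA_real_)
  k <- idx[which.max(psd)] - 1
  k * fs / nfft
}

#' Workload and timing EMG feature vector for one recording
#'
#' Runs the preprocessing chain, derives the activation threshold from the
#' recording's baseline segment, and emits the six features with their
#' canonical column names: `CMW`, `AWS`, `TotalTime`, `RMS`, `Range`,
#' `DominantFreq`.  `RMS`, `Range` and `DominantFreq` are computed on the
#' filtered (detrended, band-passed, notched) signal; `CMW`, `AWS` and
#' `TotalTime` on the MVC-normalized envelope.
#'
#' @param rec [recording].
#' @param ... preprocessing overrides passed to [preprocess_emg()].
#' @return named numeric vector of the six features.
#' @export
emg_feature_vector <- function(rec, ...) {
  env <- preprocess_emg(rec$emg, rec$mvc_value, keep_filtered = TRUE, ...)
  filtered <- attr(env, "filtered")
  base_env <- preprocess_emg(rec$baseline_emg, rec$mvc_value, ...)
  thr <- compute_threshold(base_env)
  act <- detect_activity(env, thr)
  cmw <- cumulative_muscular_workload(env)
  duration <- length(env$samples) / env$fs
  c(CMW = cmw,
    AWS = average_work_per_second(cmw, duration),
    TotalTime = act$total_time,
    RMS = emg_rms(filtered),
    Range = signal_range(filtered),
    DominantFreq = dominant_frequency(filtered))
}
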