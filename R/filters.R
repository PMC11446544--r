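# Butterworth filtering front-ends. Offline paths are zero-phase
# (forward-backward); the streaming path is causal so every output sample
# depends only on past inputs.

butter_coefs <- function(order, W, type) {
  flt <- signal::butter(order, W, type = type)
  list(b = as.numeric(flt$b), a = as.numeric(flt$a))
}

apply_filter <- function(record, coefs, causal) {
  y <- if (causal) {
    iir_filter(coefs$b, coefs$a, record$samples)$y
  } else {
    as.numeric(signal::filtfilt(signal::Arma(b = coefs$b, a = coefs$a),
                                record$samples))
  }
  ecg_record(y, record$fs, record$start_time)
}

#' QRS-band bandpass filter (5-15 Hz)
#'
#' Second-order Butterworth bandpass used ahead of R-peak detection. The
#' passband brackets QRS energy while rejecting baseline wander, T-waves
#' and mains interference. Zero-phase by default (offline analysis); set
#' `causal = TRUE` for the streaming-equivalent single-pass filter.
#'
#' @param record An [ecg_record()].
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param causal If `TRUE`, apply the filter forward only (causal); if
#'   `FALSE` (default), forward-backward for zero phase.
#' @return A filtered [ecg_record()].
#' @export
bandpass <- function(record, low = 5, high = 15, causal = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  nyq <- record$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  apply_filter(record, butter_coefs(2, c(low, high) / nyq, "pass"), causal)
}

#' Baseline-wander removal (0.5 Hz high-pass)
#'
#' Second-order Butterworth high-pass used before offline delineation, so
#' that slow electrode drift does not bias T-wave amplitude thresholds.
#'
#' @param record An [ecg_record()].
#' @param cutoff High-pass cutoff in Hz; `0 < cutoff < fs/2`.
#' @param causal Forward-only filtering if `TRUE`; zero-phase otherwise.
#' @return A filtered [ecg_record()].
#' @export
highpass_clean <- function(record, cutoff = 0.5, causal = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  nyq <- record$fs / 2
  if (!(cutoff > 0 && cutoff < nyq))
    stop("`cutoff` must lie in (0, fs/2)", call. = FALSE)
  apply_filter(record, butter_coefs(2, cutoff / nyq, "high"), causal)
}
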