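#' ECG recording container
#'
#' A single-channel ECG recording: an amplitude vector with its sampling
#' rate and the time of the first sample. All downstream operations
#' (filtering, R-peak detection, delineation, pulse replay) take this
#' container.
#'
#' @param samples Numeric vector of ECG amplitudes (arbitrary units).
#' @param fs Sampling rate in Hz; must be positive.
#' @param start_time Time of the first sample in seconds (default 0).
#' @return An object of class `ecg_record` with elements `samples`, `fs`,
#'   `start_time`.
#' @export
ecg_record <- function(samples, fs, start_time = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (anyNA(samples) || !all(is.finite(samples)))
    stop("`samples` must be finite and non-missing", call. = FALSE)
  structure(
    list(samples = samples, fs = fs, start_time = as.numeric(start_time)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record> %d samples @ %g Hz (%.1f s from t = %.3f s)\n",
    length(x$samples), x$fs, length(x$samples) / x$fs, x$start_time
  ))
  invisible(x)
}

# Time axis of a recording, in seconds.
record_times <- function(record) {
  record$start_time + (seq_along(record$samples) - 1) / record$fs
}

#' Ordered R-peak train
#'
#' Strictly increasing R-peak times for one recording. Enforces the
#' physiological refractory constraint that no two peaks are closer than
#' 0.2 s.
#'
#' @param times Numeric vector of R-peak times (seconds), strictly
#'   increasing.
#' @param fs Sampling rate (Hz) of the recording the peaks came from;
#'   provenance only, may be `NA` for analytically constructed trains.
#' @return An object of class `rpeak_train` with elements `times` and `fs`.
#' @export
rpeak_train <- function(times, fs = NA_real_) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("R-peak times must be non-missing", call. = FALSE)
  if (length(times) > 1L) {
    d <- diff(times)
    if (any(d <= 0)) stop("R-peak times must be strictly increasing", call. = FALSE)
    if (min(d) < 0.2 - 1e-9)
      stop("R-peak train violates the 0.2 s refractory period", call. = FALSE)
  }
  structure(list(times = times, fs = fs), class = "rpeak_train")
}

#' @export
print.rpeak_train <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<rpeak_train> %d peaks", n))
  if (n > 1L)
    cat(sprintf(", mean R-R %.3f s", mean(diff(x$times))))
  cat("\n")
  invisible(x)
}

#' Paired R-peak / T-wave-offset events
#'
#' Per-beat fiducial times defining the systole/diastole split: systole
#' runs from the R-peak to the same beat's T-wave offset, diastole from the
#' T-wave offset to the next R-peak. The T-wave offset of a beat may be
#' missing (`NA`) -- typically the last beat, whose T-wave is truncated.
#'
#' @param r_times Numeric vector of R-peak times (seconds), strictly
#'   increasing.
#' @param t_offsets Numeric vector of T-wave-offset times, one per beat
#'   (`NA` where undetermined). Wherever defined,
#'   `r_times[i] < t_offsets[i] < r_times[i + 1]` must hold.
#' @return An object of class `cardiac_events`.
#' @export
cardiac_events <- function(r_times, t_offsets) {
  r_times <- as.numeric(r_times)
  t_offsets <- as.numeric(t_offsets)
  if (length(t_offsets) != length(r_times))
    stop("`t_offsets` must have one entry per beat", call. = FALSE)
  if (is.unsorted(r_times, strictly = TRUE))
    stop("`r_times` must be strictly increasing", call. = FALSE)
  n <- length(r_times)
  next_r <- c(r_times[-1L], Inf)
  ok <- which(!is.na(t_offsets))
  if (any(t_offsets[ok] <= r_times[ok] | t_offsets[ok] >= next_r[ok]))
    stop("T-offsets must lie strictly between consecutive R-peaks", call. = FALSE)
  structure(list(r_times = r_times, t_offsets = t_offsets),
            class = "cardiac_events")
}

#' @export
print.cardiac_events <- function(x, ...) {
  cat(sprintf("<cardiac_events> %d beats, %d with T-offset\n",
              length(x$r_times), sum(!is.na(x$t_offsets))))
  invisible(x)
}

#' Ground-truth cardiac events of a simulated recording
#'
#' @param record An `ecg_record` produced by [simulate_ecg()].
#' @return The [cardiac_events()] object the simulator embedded, or `NULL`
#'   for recordings without ground truth.
#' @export
true_events <- function(record) attr(record, "true_events")
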