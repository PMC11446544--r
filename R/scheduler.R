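# Cardiac-phase-locked pulse scheduling. From a stream of detected
# R-peaks, build the commanded and display-truth pulse-peak times for the
# systole-entrained (in-phase) stimulus and its diastole (anti-phase)
# counterpart, plus the Gaussian pulse amplitude traces at the update and
# render rates.

#' Scheduler configuration
#'
#' @param adc_latency Analog-to-digital conversion latency of the
#'   acquisition chain (s). Pulses are commanded this much early so they
#'   peak on screen at the intended cardiac time.
#' @param target_display_peak Intended on-screen pulse peak, seconds after
#'   each R-peak; must exceed `adc_latency`.
#' @param pulse_scale Standard deviation of the Gaussian pulse (s).
#' @param update_rate Stimulus-update rate (Hz): one target-size update
#'   per acquired ECG sample.
#' @param render_rate Screen refresh rate (Hz); the rendered stimulus
#'   holds the most recent update value.
#' @return A validated list of class `scheduler_config`.
#' @export
scheduler_config <- function(adc_latency = 0.035,
                             target_display_peak = 0.210,
                             pulse_scale = 1 / 16,
                             update_rate = 100,
                             render_rate = 60) {
  stopifnot(
    adc_latency >= 0, target_display_peak > adc_latency,
    pulse_scale > 0, update_rate > 0, render_rate > 0
  )
  structure(
    list(adc_latency = adc_latency,
         target_display_peak = target_display_peak,
         pulse_scale = pulse_scale,
         update_rate = update_rate,
         render_rate = render_rate),
    class = "scheduler_config"
  )
}

#' Schedule in-phase (systole-entrained) pulse peaks
#'
#' One pulse per detected R-peak. The display-truth peak is
#' `R + target_display_peak`; the commanded peak is issued `adc_latency`
#' earlier (`R + target_display_peak - adc_latency`) so that, after the
#' acquisition latency, the on-screen pulse actually peaks at the target
#' time.
#'
#' @param rpeaks An [rpeak_train()] (nonempty).
#' @param cfg A [scheduler_config()].
#' @return A data.frame with columns `r_time`, `commanded`, `display`.
#' @export
schedule_inphase <- function(rpeaks, cfg = scheduler_config()) {
  stopifnot(inherits(rpeaks, "rpeak_train"), inherits(cfg, "scheduler_config"))
  r <- rpeaks$times
  if (length(r) == 0L) stop("`rpeaks` must be nonempty", call. = FALSE)
  data.frame(
    r_time = r,
    commanded = r + cfg$target_display_peak - cfg$adc_latency,
    display = r + cfg$target_display_peak
  )
}

#' Schedule anti-phase (diastole) pulse peaks
#'
#' The anti-phase pulse for beat `i` is delayed relative to the in-phase
#' pulse by half of the previous R-R interval,
#' `0.5 * (R_i - R_{i-1})`. The first beat has no previous interval and
#' emits no anti-phase pulse.
#'
#' @param inphase_peaks In-phase peak times (s), one per beat -- typically
#'   the `display` column of [schedule_inphase()] (or `commanded`, for
#'   commanded anti-phase times).
#' @param rpeaks The [rpeak_train()] the in-phase peaks came from (at
#'   least two peaks for a nonempty result).
#' @return Numeric vector of anti-phase peak times, one per beat from the
#'   second onward.
#' @export
schedule_antiphase <- function(inphase_peaks, rpeaks) {
  stopifnot(inherits(rpeaks, "rpeak_train"))
  r <- rpeaks$times
  if (length(inphase_peaks) != length(r))
    stop("need one in-phase peak per R-peak", call. = FALSE)
  if (length(r) < 2L) return(numeric(0))
  inphase_peaks[-1L] + 0.5 * diff(r)
}

#' Render a pulse amplitude trace
#'
#' The stimulus amplitude is a sum of unit Gaussian bells, one per pulse
#' peak: `amplitude(t) = sum_p exp(-(t - p)^2 / (2 pulse_scale^2))`,
#' evaluated on the update-rate grid over `[0, duration)` relative to
#' `origin`. The rendered trace samples-and-holds the most recent update
#' value at each render tick. If `available_from` is supplied (one time
#' per peak), the trace is causal: a pulse contributes only at grid times
#' at or after the moment it was commanded. Gaussian tails are truncated
#' at eight standard deviations.
#'
#' @param peaks Pulse peak times (s).
#' @param cfg A [scheduler_config()].
#' @param duration Trace length in seconds (> 0).
#' @param origin Time of the first grid point (default 0).
#' @param available_from Optional vector, same length as `peaks`: time
#'   from which each pulse is known to the renderer.
#' @return A list with data.frames `update` (`time`, `amplitude`) and
#'   `render` (`time`, `amplitude`).
#' @export
render_pulse_trace <- function(peaks, cfg = scheduler_config(), duration,
                               origin = 0, available_from = NULL) {
  stopifnot(inherits(cfg, "scheduler_config"))
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  tu <- origin + seq(0, duration - 1e-12, by = 1 / cfg$update_rate)
  amp <- numeric(length(tu))
  s <- cfg$pulse_scale
  half <- 8 * s
  for (j in seq_along(peaks)) {
    p <- peaks[j]
    lo_t <- p - half
    if (!is.null(available_from)) lo_t <- max(lo_t, available_from[j])
    lo <- max(1L, ceiling((lo_t - origin) * cfg$update_rate) + 1L)
    hi <- min(length(tu), floor((p + half - origin) * cfg$update_rate) + 1L)
    if (hi >= lo) {
      idx <- lo:hi
      amp[idx] <- amp[idx] + exp(-(tu[idx] - p)^2 / (2 * s^2))
    }
  }
  tr <- origin + seq(0, duration - 1e-12, by = 1 / cfg$render_rate)
  held <- findInterval(tr - origin + 1e-12, tu - origin)
  held[held < 1L] <- 1L
  list(
    update = data.frame(time = tu, amplitude = amp),
    render = data.frame(time = tr, amplitude = amp[held])
  )
}

#' Replay a recording through the full real-time chain
#'
#' Runs streaming R-peak detection, in-phase scheduling, anti-phase
#' scheduling, and (optionally) trace rendering in one causal pass over a
#' recording -- the software equivalent of the online stimulus pipeline.
#' Output equals composing [detect_rpeaks()] (streaming),
#' [schedule_inphase()], [schedule_antiphase()] and
#' [render_pulse_trace()] by hand.
#'
#' @param record An [ecg_record()].
#' @param cfg A [scheduler_config()].
#' @param trace Also render amplitude traces (default `FALSE`; they are
#'   large for long recordings).
#' @return A list of class `pulse_schedule`: `rpeaks`, `inphase`
#'   (data.frame `r_time`/`commanded`/`display`), `antiphase` (data.frame
#'   `commanded`/`display`), and, when `trace = TRUE`, `inphase_trace` and
#'   `antiphase_trace`. Empty detection yields an empty schedule.
#' @export
replay_session <- function(record, cfg = scheduler_config(), trace = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  rpeaks <- suppressWarnings(detect_rpeaks(record, streaming = TRUE))
  if (length(rpeaks$times) == 0L) {
    empty <- data.frame(commanded = numeric(0), display = numeric(0))
    return(structure(list(rpeaks = rpeaks,
                          inphase = cbind(r_time = numeric(0), empty),
                          antiphase = empty),
                     class = "pulse_schedule"))
  }
  inphase <- schedule_inphase(rpeaks, cfg)
  anti <- data.frame(
    commanded = schedule_antiphase(inphase$commanded, rpeaks),
    display = schedule_antiphase(inphase$display, rpeaks)
  )
  out <- list(rpeaks = rpeaks, inphase = inphase, antiphase = anti)
  if (trace) {
    dur <- length(record$samples) / record$fs
    # a pulse is known to the renderer from the R-peak that commands it
    out$inphase_trace <- render_pulse_trace(
      inphase$display, cfg, dur, origin = record$start_time,
      available_from = inphase$r_time
    )
    out$antiphase_trace <- if (nrow(anti)) render_pulse_trace(
      anti$display, cfg, dur, origin = record$start_time,
      available_from = inphase$r_time[-1L]
    ) else NULL
  }
  structure(out, class = "pulse_schedule")
}

#' @export
print.pulse_schedule <- function(x, ...) {
  cat(sprintf("<pulse_schedule> %d in-phase, %d anti-phase pulses\n",
              nrow(x$inphase), nrow(x$antiphase)))
  invisible(x)
}
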