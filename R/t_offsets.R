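# Offline T-wave offset delineation.
#
# A threshold-on-the-descending-limb delineator: for each beat the T-wave
# extremum is located in a physiological search window, and the offset is
# the first sample after the extremum at which the (cleaned, lightly
# smoothed) signal drops below 10% of the T amplitude. Deliberately simple
# and fully characterized against synthetic ground truth; it does not aim
# to reproduce any particular published wavelet delineator.

#' Delineate T-wave offsets
#'
#' For each beat `i` with successor, searches the window
#' `(R_i + 0.15 s, R_i + 0.6 (R_{i+1} - R_i))` of the baseline-corrected
#' signal for the T-wave extremum, then walks forward to the first sample
#' whose amplitude (relative to baseline, same polarity as the extremum)
#' falls below 10% of the T amplitude. Beats where the R-R interval is
#' shorter than 0.25 s, where the search window is empty, or where the
#' threshold is never crossed before the next R-peak get a missing offset,
#' as does the final beat (no successor).
#'
#' @param record An [ecg_record()] (raw; baseline correction is applied
#'   internally via [highpass_clean()]).
#' @param rpeaks An [rpeak_train()] with at least two peaks.
#' @return A [cardiac_events()] object with one (possibly missing)
#'   T-offset per beat.
#' @export
detect_t_offsets <- function(record, rpeaks) {
  stopifnot(inherits(record, "ecg_record"), inherits(rpeaks, "rpeak_train"))
  r <- rpeaks$times
  if (length(r) < 2L) stop("need at least two R-peaks", call. = FALSE)
  fs <- record$fs
  clean <- highpass_clean(record, 0.5)$samples
  # light smoothing so sample noise does not trigger the 10% threshold early
  w <- max(3L, round(0.07 * fs))
  if (w %% 2L == 0L) w <- w + 1L
  s <- as.numeric(stats::filter(clean, rep(1 / w, w), sides = 2))
  s[is.na(s)] <- clean[is.na(s)]
  t0 <- record$start_time
  at <- function(time) pmin(pmax(round((time - t0) * fs) + 1L, 1L), length(s))

  n <- length(r)
  t_off <- rep(NA_real_, n)
  for (i in seq_len(n - 1L)) {
    rr <- r[i + 1L] - r[i]
    if (rr < 0.25) next
    lo <- at(r[i] + 0.15)
    hi <- at(r[i] + 0.6 * rr)
    if (hi <= lo) next
    limit <- at(r[i + 1L]) - 1L     # never cross into the next beat
    # diastolic baseline just before the next beat (the high-pass leaves a
    # slight undershoot after the T-wave; measuring amplitude against this
    # baseline keeps the 10% threshold unbiased)
    b_lo <- max(lo, limit - round(0.1 * fs))
    base <- stats::median(s[b_lo:limit])
    win <- s[lo:hi] - base
    pk <- which.max(abs(win))
    amp <- win[pk]
    if (!is.finite(amp) || amp == 0) next
    sgn <- sign(amp)
    j <- lo + pk - 1L
    found <- NA_integer_
    while (j < limit) {
      j <- j + 1L
      if ((s[j] - base) * sgn < 0.1 * abs(amp)) { found <- j; break }
    }
    if (is.na(found)) next
    cand <- t0 + (found - 1L) / fs
    if (cand > r[i] && cand < r[i + 1L]) t_off[i] <- cand
  }
  cardiac_events(r, t_off)
}
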