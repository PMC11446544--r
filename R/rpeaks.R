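# Streaming Pan-Tompkins R-peak detection.
#
# Chain: causal 5-15 Hz bandpass -> five-point derivative -> squaring ->
# 150 ms moving-window integration (MWI). Detection logic runs on local
# maxima of the MWI signal with the canonical adaptive signal/noise
# thresholds (0.125/0.875 updates), a 200 ms refractory period, and
# search-back at 1.66 times the running R-R average (0.25/0.75 update for
# search-back peaks). Each accepted MWI peak is mapped back to the R-peak
# proper by locating the largest absolute raw deflection in a short
# look-back window, which also removes the causal filter delay. Every
# decision uses only samples already seen, so the detector can be fed in
# arbitrary chunks and carries exact state between calls.

PT_REFRACTORY <- 0.2    # s, absolute refractory between accepted peaks
PT_MWI_WINDOW <- 0.15   # s, moving-window integration length
PT_SEARCHBACK <- 1.66   # multiple of running R-R that triggers search-back
PT_INIT_SECS  <- 2      # s, threshold initialization window
PT_LOOKBACK   <- 0.25   # s, raw-signal window for R refinement

#' Stateful Pan-Tompkins detector
#'
#' Low-level streaming interface: create a detector for a given sampling
#' rate, feed it ECG samples in chunks with `$process()`, and read the
#' R-peak times found so far with `$peaks()`. [detect_rpeaks()] is the
#' high-level wrapper. Chunk boundaries never change the result: feeding
#' the signal sample-by-sample, second-by-second, or all at once yields
#' identical peak trains.
#'
#' @param fs Sampling rate in Hz (>= 50 so the QRS complex is resolved).
#' @param start_time Time of the first sample that will be fed (seconds).
#' @return A list with functions `process(samples)` (returns, invisibly,
#'   R-peak times newly emitted by this chunk), `peaks()` (all R-peak times
#'   so far) and `n_seen()` (samples consumed).
#' @export
rpeak_detector <- function(fs, start_time = 0) {
  if (fs < 50) stop("`fs` too low to resolve the QRS complex", call. = FALSE)
  nyq <- fs / 2
  bp <- butter_coefs(2, c(5, 15) / nyq, "pass")
  der <- list(b = c(2, 1, 0, -1, -2) / 8, a = 1)
  mwi_n <- max(2L, round(PT_MWI_WINDOW * fs))
  mwi <- list(b = rep(1 / mwi_n, mwi_n), a = 1)
  refr_n <- round(PT_REFRACTORY * fs)
  look_n <- round(PT_LOOKBACK * fs)
  init_n <- round(PT_INIT_SECS * fs)
  buf_n <- round(3 * fs)

  st <- new.env(parent = emptyenv())
  st$idx <- 0L                      # samples consumed
  st$s_bp <- NULL; st$s_der <- NULL; st$s_mwi <- NULL
  st$m_hist <- numeric(0)           # last two MWI samples (global tail)
  st$raw <- numeric(0)              # raw ring buffer
  st$raw_first <- 1L                # global index of raw[1]
  st$init_done <- FALSE
  st$mwi_max <- -Inf; st$mwi_sum <- 0; st$mwi_cnt <- 0L
  st$init_cands <- list()
  st$spki <- NA_real_; st$npki <- NA_real_
  st$noise_idx <- integer(0); st$noise_val <- numeric(0)
  st$last_qrs <- NA_integer_        # MWI-peak index of last accepted QRS
  st$peaks <- integer(0)            # refined R sample indices
  st$rr <- numeric(0)               # last 8 R-R intervals (s)

  threshold1 <- function() st$npki + 0.25 * (st$spki - st$npki)

  refine_r <- function(ci) {
    lo <- max(ci - look_n, st$raw_first)
    hi <- min(ci, st$raw_first + length(st$raw) - 1L)
    w <- st$raw[(lo - st$raw_first + 1L):(hi - st$raw_first + 1L)]
    lo + which.max(abs(w - mean(w))) - 1L
  }

  accept_qrs <- function(ci, cv, searchback = FALSE) {
    st$spki <- if (searchback) 0.25 * cv + 0.75 * st$spki
               else            0.125 * cv + 0.875 * st$spki
    st$last_qrs <- ci
    keep <- st$noise_idx > ci
    st$noise_idx <- st$noise_idx[keep]; st$noise_val <- st$noise_val[keep]
    r_idx <- refine_r(ci)
    np <- length(st$peaks)
    if (np == 0L || (r_idx - st$peaks[np]) >= refr_n) {
      if (np > 0L) {
        st$rr <- c(st$rr, (r_idx - st$peaks[np]) / fs)
        if (length(st$rr) > 8L) st$rr <- st$rr[-1L]
      }
      st$peaks <- c(st$peaks, r_idx)
    }
  }

  try_searchback <- function(ci) {
    repeat {
      if (length(st$rr) < 2L || is.na(st$last_qrs)) return(invisible())
      if ((ci - st$last_qrs) / fs <= PT_SEARCHBACK * mean(st$rr)) return(invisible())
      sel <- st$noise_idx > st$last_qrs + refr_n & st$noise_idx < ci - refr_n
      if (!any(sel)) return(invisible())
      j <- which(sel)[which.max(st$noise_val[sel])]
      if (st$noise_val[j] <= 0.5 * threshold1()) return(invisible())
      accept_qrs(st$noise_idx[j], st$noise_val[j], searchback = TRUE)
    }
  }

  handle_candidate <- function(ci, cv) {
    try_searchback(ci)
    if (!is.na(st$last_qrs) && (ci - st$last_qrs) < refr_n) return(invisible())
    if (cv > threshold1()) {
      accept_qrs(ci, cv)
    } else {
      st$npki <- 0.125 * cv + 0.875 * st$npki
      st$noise_idx <- c(st$noise_idx, ci)
      st$noise_val <- c(st$noise_val, cv)
      if (length(st$noise_idx) > 100L) {
        st$noise_idx <- st$noise_idx[-1L]; st$noise_val <- st$noise_val[-1L]
      }
    }
  }

  process_core <- function(samples) {
    n <- length(samples)
    n_before <- length(st$peaks)

    f1 <- iir_filter(bp$b, bp$a, samples, st$s_bp);  st$s_bp <- f1$state
    f2 <- iir_filter(der$b, der$a, f1$y, st$s_der);  st$s_der <- f2$state
    f3 <- iir_filter(mwi$b, mwi$a, f2$y^2, st$s_mwi); st$s_mwi <- f3$state
    m <- f3$y

    # raw ring buffer for R refinement
    st$raw <- c(st$raw, samples)
    if (length(st$raw) > buf_n) {
      drop <- length(st$raw) - buf_n
      st$raw <- st$raw[-seq_len(drop)]
      st$raw_first <- st$raw_first + drop
    }

    # local maxima of the MWI signal, across chunk boundaries
    nh <- length(st$m_hist)
    mm <- c(st$m_hist, m)
    if (length(mm) >= 3L) {
      p <- 2L:(length(mm) - 1L)
      is_max <- mm[p] > mm[p - 1L] & mm[p] >= mm[p + 1L]
      cand_rel <- p[is_max]
    } else cand_rel <- integer(0)
    cand_idx <- st$idx - nh + cand_rel
    cand_val <- mm[cand_rel]
    st$m_hist <- mm[seq.int(max(1L, length(mm) - 1L), length(mm))]
    st$idx <- st$idx + n

    # threshold initialization over the first seconds
    if (!st$init_done) {
      within <- cand_idx <= init_n
      if (any(within)) {
        st$init_cands <- c(st$init_cands,
                           Map(c, cand_idx[within], cand_val[within]))
      }
      upto <- min(length(m), init_n - (st$idx - n))
      if (upto > 0L) {
        st$mwi_max <- max(st$mwi_max, max(m[seq_len(upto)]))
        st$mwi_sum <- st$mwi_sum + sum(m[seq_len(upto)])
        st$mwi_cnt <- st$mwi_cnt + upto
      }
      if (st$idx >= init_n) {
        st$spki <- 0.5 * st$mwi_max
        st$npki <- 0.5 * st$mwi_sum / max(1L, st$mwi_cnt)
        st$init_done <- TRUE
        for (cnd in st$init_cands) handle_candidate(as.integer(cnd[1L]), cnd[2L])
        st$init_cands <- list()
      }
      cand_keep <- cand_idx > init_n
      cand_idx <- cand_idx[cand_keep]; cand_val <- cand_val[cand_keep]
      if (!st$init_done) return(invisible(numeric(0)))
    }

    for (k in seq_along(cand_idx)) handle_candidate(cand_idx[k], cand_val[k])

    new <- st$peaks[seq.int(n_before + 1L, length.out = length(st$peaks) - n_before)]
    start_time + (new - 1L) / fs
  }

  # Internally bound the slice length so the raw refinement buffer always
  # spans every candidate still awaiting a decision; results are
  # invariant to how callers chunk the input.
  process <- function(samples) {
    samples <- as.numeric(samples)
    n <- length(samples)
    if (n == 0L) return(invisible(numeric(0)))
    slice <- max(1L, round(fs))
    out <- vector("list", ceiling(n / slice))
    j <- 0L
    for (i in seq.int(1L, n, by = slice)) {
      j <- j + 1L
      out[[j]] <- process_core(samples[i:min(i + slice - 1L, n)])
    }
    invisible(unlist(out))
  }

  list(
    process = process,
    peaks = function() start_time + (st$peaks - 1L) / fs,
    n_seen = function() st$idx
  )
}

#' Detect R-peaks with the Pan-Tompkins algorithm
#'
#' Runs the full detection chain (bandpass, derivative, squaring,
#' moving-window integration, adaptive thresholding with refractory and
#' search-back) over a recording. In streaming mode the recording is fed
#' to the stateful detector one second at a time, so every emitted peak
#' depends only on past samples; batch mode feeds the whole recording in
#' one call. The two modes yield identical peak trains by construction of
#' the carried state.
#'
#' @param record An [ecg_record()] at least 2 s long.
#' @param streaming Process in 1 s chunks (`TRUE`) or one pass (`FALSE`).
#' @return An [rpeak_train()]. A flat (zero-variance) signal yields an
#'   empty train with a warning.
#' @export
detect_rpeaks <- function(record, streaming = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  n <- length(record$samples)
  if (n / record$fs < 2)
    stop("recording must be at least 2 s long", call. = FALSE)
  if (stats::sd(record$samples) == 0) {
    warning("flat signal: no R-peaks detected", call. = FALSE)
    return(rpeak_train(numeric(0), record$fs))
  }
  det <- rpeak_detector(record$fs, record$start_time)
  if (streaming) {
    chunk <- max(1L, round(record$fs))
    for (i in seq.int(1L, n, by = chunk))
      det$process(record$samples[i:min(i + chunk - 1L, n)])
  } else {
    det$process(record$samples)
  }
  pk <- det$peaks()
  if (length(pk) == 0L)
    warning("no R-peaks detected", call. = FALSE)
  rpeak_train(pk, record$fs)
}
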