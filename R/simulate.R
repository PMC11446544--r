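# Synthetic cohort generators. These define the study conditions the
# analysis stages are tested under: autocorrelated sinus rhythm, a
# delineatable two-wave ECG template, gamma-distributed alternating
# dominance intervals with a multiplicative systole effect, and the
# two-component discrimination mixture.

#' Simulate an R-R interval series
#'
#' Beat-to-beat R-R intervals follow a stationary AR(1) Gaussian process
#' around `mean_rr` (marginal SD `rr_sd`, nonnegative autocorrelation
#' `ar`), floored at `min_rr` so pathological short intervals cannot
#' occur. `rr_sd = 0` gives a perfectly regular train.
#'
#' @param mean_rr Mean R-R interval (s); must exceed `3 * rr_sd`.
#' @param rr_sd Marginal SD of R-R intervals (s), `>= 0`.
#' @param duration Recording length (s); R-peaks cover `[0, duration]`.
#' @param seed Optional integer seed (fixed seed implies identical trains).
#' @param ar First-order autocorrelation of the R-R series, in `[0, 1)`.
#' @param min_rr Hard floor on R-R intervals (s).
#' @return An [rpeak_train()] starting at time 0.
#' @export
simulate_rr_series <- function(mean_rr, rr_sd, duration, seed = NULL,
                               ar = 0.3, min_rr = 0.3) {
  if (!is.numeric(duration) || duration <= 0)
    stop("`duration` must be positive", call. = FALSE)
  if (rr_sd < 0 || (rr_sd > 0 && mean_rr <= 3 * rr_sd))
    stop("need mean_rr > 3 * rr_sd >= 0", call. = FALSE)
  if (ar < 0 || ar >= 1) stop("`ar` must be in [0, 1)", call. = FALSE)
  n <- ceiling(duration / min(mean_rr, min_rr)) + 10L
  rr <- with_seed(seed, {
    if (rr_sd == 0) rep(mean_rr, n)
    else {
      e <- stats::rnorm(n, 0, rr_sd * sqrt(1 - ar^2))
      dev0 <- stats::rnorm(1, 0, rr_sd)
      dev <- as.numeric(stats::filter(e, ar, method = "recursive", init = dev0))
      pmax(mean_rr + dev, min_rr)
    }
  })
  times <- c(0, cumsum(rr))
  rpeak_train(times[times <= duration + 1e-9])
}

# ECG beat template, fractions of the local R-R interval (see vignette):
# QRS is a narrow Gaussian at each R-peak; the T-wave a broader, smaller
# Gaussian whose offset (center + 2 sigma) is the ground-truth end of
# systole. At the default 0.8 s R-R this puts the T center 250 ms and the
# T-offset 370 ms after the R-peak.
ECG_QRS_SIGMA <- 0.015   # s (absolute; QRS width does not track heart rate)
ECG_T_CENTER  <- 0.3125  # fraction of R-R
ECG_T_SIGMA   <- 0.075   # fraction of R-R
ECG_T_AMP     <- 0.3     # relative to unit QRS amplitude

#' Simulate an ECG waveform from an R-peak train
#'
#' Renders a beat-template sum (unit-amplitude Gaussian QRS at each R-peak
#' plus a broader low-amplitude T-wave) sampled at `fs`, with additive
#' white Gaussian noise. The exact T-wave offsets used by the template are
#' attached as ground truth and can be read back with [true_events()];
#' they always satisfy `R_i < T_i < R_{i+1}` (the final beat, lacking a
#' successor, has no T event).
#'
#' @param rpeaks An [rpeak_train()] (nonempty).
#' @param fs Sampling rate in Hz, `>= 50`.
#' @param noise_sd SD of additive white noise, in units of the QRS
#'   amplitude (which is 1).
#' @param seed Optional integer seed for the noise.
#' @return An [ecg_record()] with a `true_events` attribute.
#' @export
simulate_ecg <- function(rpeaks, fs = 100, noise_sd = 0.05, seed = NULL) {
  stopifnot(inherits(rpeaks, "rpeak_train"))
  r <- rpeaks$times
  if (length(r) == 0L) stop("`rpeaks` must be nonempty", call. = FALSE)
  if (fs < 50) stop("`fs` too low to resolve the QRS complex", call. = FALSE)
  dur <- max(r) + 0.2
  t <- seq(0, dur, by = 1 / fs)
  x <- numeric(length(t))
  add_gauss <- function(center, sigma, amp) {
    lo <- max(1L, floor((center - 6 * sigma) * fs) + 1L)
    hi <- min(length(t), ceiling((center + 6 * sigma) * fs) + 1L)
    if (hi >= lo) {
      idx <- lo:hi
      x[idx] <<- x[idx] + amp * exp(-(t[idx] - center)^2 / (2 * sigma^2))
    }
  }
  n <- length(r)
  t_off <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    add_gauss(r[i], ECG_QRS_SIGMA, 1)
    if (i < n) {
      rr <- r[i + 1L] - r[i]
      add_gauss(r[i] + ECG_T_CENTER * rr, ECG_T_SIGMA * rr, ECG_T_AMP)
      t_off[i] <- r[i] + (ECG_T_CENTER + 2 * ECG_T_SIGMA) * rr
    }
  }
  if (noise_sd > 0)
    x <- x + with_seed(seed, stats::rnorm(length(x), 0, noise_sd))
  rec <- ecg_record(x, fs, start_time = 0)
  attr(rec, "true_events") <- cardiac_events(r, t_off)
  rec
}

#' Simulate one subject's rivalry session
#'
#' Dominance intervals alternate between the systole-entrained and the
#' diastole-entrained grating. Durations are gamma with fixed shape and
#' mean `mean_dominance * exp(subject_effect) * (1 + systole_effect)` for
#' the systole condition (no `(1 + systole_effect)` factor in diastole).
#' Intervals tile each block exactly; the final interval of a block is
#' truncated at the block boundary and flagged `censored`. The mapping of
#' eyes to conditions swaps between blocks (counterbalancing), and the
#' starting percept of each block is random.
#'
#' @param cfg A [cohort_config()].
#' @param subject_effect Subject-level log-scale effect on mean dominance.
#' @param seed Optional integer seed.
#' @param subject Subject label for the output table.
#' @return A data.frame with columns `subject`, `block`, `onset`,
#'   `duration`, `eye`, `condition`, `censored` (the dominance table
#'   schema).
#' @export
simulate_rivalry_session <- function(cfg, subject_effect = 0, seed = NULL,
                                     subject = "sub-01") {
  stopifnot(inherits(cfg, "cohort_config"))
  base_mean <- cfg$mean_dominance * exp(subject_effect)
  mean_by_cond <- c(systole = base_mean * (1 + cfg$systole_effect),
                    diastole = base_mean)
  with_seed(seed, {
    blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
      systole_eye <- if (b %% 2L == 1L) "left" else "right"
      first <- sample(c("systole", "diastole"), 1L)
      n_draw <- ceiling(1.7 * cfg$block_duration / min(mean_by_cond)) + 20L
      repeat {
        cond <- rep(
          if (first == "systole") c("systole", "diastole")
          else c("diastole", "systole"),
          length.out = n_draw
        )
        d <- stats::rgamma(n_draw, shape = cfg$gamma_shape,
                           scale = mean_by_cond[cond] / cfg$gamma_shape)
        if (sum(d) >= cfg$block_duration) break
        n_draw <- n_draw * 2L
      }
      ends <- cumsum(d)
      keep <- seq_len(which(ends >= cfg$block_duration)[1L])
      d <- d[keep]; cond <- cond[keep]
      onset <- c(0, ends[keep[-length(keep)]])
      censored <- logical(length(keep))
      censored[length(keep)] <- TRUE
      d[length(keep)] <- cfg$block_duration - onset[length(keep)]
      data.frame(
        subject = subject, block = b, onset = onset, duration = d,
        eye = ifelse(cond == "systole", systole_eye,
                     setdiff(c("left", "right"), systole_eye)),
        condition = cond, censored = censored,
        stringsAsFactors = FALSE, row.names = NULL
      )
    })
    do.call(rbind, blocks)
  })
}

#' Simulate a full rivalry cohort
#'
#' Draws one log-normal subject random effect per subject
#' (`N(0, subject_sd)` on the log scale) and simulates each subject's
#' session on an independent substream of the root seed, so results do not
#' depend on subject iteration order.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer root seed.
#' @return A dominance table (row-bound [simulate_rivalry_session()]
#'   outputs) with a `subject_effects` attribute holding the latent
#'   effects.
#' @export
simulate_rivalry_cohort <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "cohort_config"))
  ids <- sprintf("sub-%02d", seq_len(cfg$n_subjects))
  u <- with_seed(substream_seed(seed, 0L),
                 stats::rnorm(cfg$n_subjects, 0, cfg$subject_sd))
  tabs <- lapply(seq_len(cfg$n_subjects), function(i) {
    simulate_rivalry_session(cfg, subject_effect = u[i],
                             seed = substream_seed(seed, i),
                             subject = ids[i])
  })
  out <- do.call(rbind, tabs)
  attr(out, "subject_effects") <- stats::setNames(u, ids)
  out
}

#' Simulate heartbeat-discrimination outcomes for a cohort
#'
#' Each subject is latently above-chance with probability
#' `cfg$prevalence`. At-chance subjects answer each of the
#' `cfg$n_discrim_trials` trials correctly with probability 0.5; an
#' above-chance subject first draws a personal accuracy
#' `p = 0.5 + Beta(alpha, beta)/2` and then answers with probability `p`.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed.
#' @return A data.frame with columns `subject`, `k` (correct trials), `n`
#'   (trials), `accuracy`, and the latent ground-truth flag
#'   `above_chance`.
#' @export
simulate_discrimination <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(seed, {
    ns <- cfg$n_subjects
    z <- stats::runif(ns) < cfg$prevalence
    p <- rep(0.5, ns)
    if (any(z))
      p[z] <- 0.5 + stats::rbeta(sum(z), cfg$alpha, cfg$beta) / 2
    k <- stats::rbinom(ns, cfg$n_discrim_trials, p)
    data.frame(
      subject = sprintf("sub-%02d", seq_len(ns)),
      k = k, n = cfg$n_discrim_trials, accuracy = k / cfg$n_discrim_trials,
      above_chance = z, stringsAsFactors = FALSE
    )
  })
}

#' Draw subject mean R-R intervals from the population law
#'
#' Truncated-normal draws: `N(mean_rr, mean_rr_sd)` restricted to
#' `cfg$rr_range` (the spec'd 60-100 bpm band by default).
#'
#' @param cfg A [cohort_config()].
#' @param n Number of subjects (defaults to `cfg$n_subjects`).
#' @param seed Optional integer seed.
#' @return Numeric vector of mean R-R intervals in seconds.
#' @export
draw_subject_mean_rr <- function(cfg, n = cfg$n_subjects, seed = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(seed, {
    lo <- cfg$rr_range[1L]; hi <- cfg$rr_range[2L]
    if (cfg$mean_rr_sd == 0) return(rep(cfg$mean_rr, n))
    u <- stats::runif(n,
                      stats::pnorm(lo, cfg$mean_rr, cfg$mean_rr_sd),
                      stats::pnorm(hi, cfg$mean_rr, cfg$mean_rr_sd))
    stats::qnorm(u, cfg$mean_rr, cfg$mean_rr_sd)
  })
}
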