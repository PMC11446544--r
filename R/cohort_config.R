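#' Cohort configuration for the synthetic-data generator
#'
#' Bundles the generative parameters for a full simulated study cohort:
#' cardiac rhythm, rivalry block structure, the multiplicative
#' systole-entrainment effect on dominance durations, and the mixture law
#' of heartbeat-discrimination accuracy. Defaults mirror the study design
#' this package analyzes (two 10-min rivalry blocks, 120 discrimination
#' trials) and conventional physiology/rivalry values elsewhere; see the
#' methods vignette for the rationale behind each default.
#'
#' @param n_subjects Number of subjects.
#' @param n_blocks Rivalry blocks per subject.
#' @param block_duration Block length in seconds.
#' @param mean_rr Population mean of subjects' mean R-R interval (s).
#' @param mean_rr_sd Between-subject SD of the mean R-R interval (s);
#'   subject means are drawn from a normal truncated to `rr_range`.
#' @param rr_range Admissible range of subject mean R-R intervals (s).
#' @param rr_sd Within-subject beat-to-beat R-R SD (s).
#' @param gamma_shape Shape of the gamma law of dominance durations.
#' @param mean_dominance Baseline mean dominance duration (s).
#' @param systole_effect Multiplicative effect of systole entrainment on
#'   the mean dominance duration (mean is scaled by `1 + systole_effect`);
#'   must exceed -1.
#' @param subject_sd SD of the subject-level log-scale random effect on
#'   mean dominance duration.
#' @param n_discrim_trials Heartbeat-discrimination trials per subject.
#' @param prevalence Population proportion of above-chance perceivers, in
#'   `[0, 1]`.
#' @param alpha,beta Shape parameters of the shifted-Beta law of
#'   above-chance accuracy, `p = 0.5 + Beta(alpha, beta)/2`.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 54,
                          n_blocks = 2,
                          block_duration = 600,
                          mean_rr = 0.8,
                          mean_rr_sd = 0.07,
                          rr_range = c(0.6, 1.0),
                          rr_sd = 0.05,
                          gamma_shape = 4,
                          mean_dominance = 2.5,
                          systole_effect = 0.0264,
                          subject_sd = 0.3,
                          n_discrim_trials = 120,
                          prevalence = 0.0948,
                          alpha = 2,
                          beta = 4) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_blocks = as.integer(n_blocks),
    block_duration = block_duration, mean_rr = mean_rr,
    mean_rr_sd = mean_rr_sd, rr_range = rr_range, rr_sd = rr_sd,
    gamma_shape = gamma_shape, mean_dominance = mean_dominance,
    systole_effect = systole_effect, subject_sd = subject_sd,
    n_discrim_trials = as.integer(n_discrim_trials),
    prevalence = prevalence, alpha = alpha, beta = beta
  )
  with(cfg, {
    stopifnot(
      n_subjects >= 1, n_blocks >= 1,
      block_duration > 0, mean_rr > 0, rr_sd >= 0, mean_rr_sd >= 0,
      gamma_shape > 0, mean_dominance > 0, systole_effect > -1,
      subject_sd >= 0, n_discrim_trials >= 1,
      prevalence >= 0, prevalence <= 1, alpha > 0, beta > 0
    )
  })
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    paste0("<cohort_config> %d subjects, %d x %g s rivalry blocks\n",
           "  dominance: gamma(shape %g, mean %g s), systole effect %+.4f,",
           " subject log-SD %g\n",
           "  discrimination: %d trials, prevalence %.3f,",
           " accuracy 0.5 + Beta(%g, %g)/2\n"),
    x$n_subjects, x$n_blocks, x$block_duration,
    x$gamma_shape, x$mean_dominance, x$systole_effect, x$subject_sd,
    x$n_discrim_trials, x$prevalence, x$alpha, x$beta
  ))
  invisible(x)
}
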