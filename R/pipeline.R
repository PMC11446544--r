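# End-to-end glue: from a raw recording to stimulus cardiac angles, and
# from a full cohort to every reported analysis.

#' Cardiac angles of the pulses a recording would have produced
#'
#' The closed loop of the real-time and offline chains: streaming R-peak
#' detection and pulse scheduling ([replay_session()]), then offline
#' delineation ([detect_t_offsets()]) and the angle map
#' ([cardiac_angle()]) applied to the display-truth pulse peak times.
#'
#' @param record An [ecg_record()].
#' @param cfg A [scheduler_config()].
#' @return A data.frame with columns `stimulus` (`inphase`/`antiphase`)
#'   and `angle` (radians).
#' @export
subject_pulse_angles <- function(record, cfg = scheduler_config()) {
  sched <- replay_session(record, cfg)
  if (length(sched$rpeaks$times) < 2L)
    return(data.frame(stimulus = character(0), angle = numeric(0)))
  events <- detect_t_offsets(record, sched$rpeaks)
  keep_in <- sched$inphase$display >= min(events$r_times) &
    sched$inphase$display <= max(events$r_times)
  keep_an <- sched$antiphase$display >= min(events$r_times) &
    sched$antiphase$display <= max(events$r_times)
  a_in <- cardiac_angle(sched$inphase$display[keep_in], events)
  a_an <- cardiac_angle(sched$antiphase$display[keep_an], events)
  rbind(
    data.frame(stimulus = rep("inphase", length(a_in)), angle = as.numeric(a_in)),
    data.frame(stimulus = rep("antiphase", length(a_an)), angle = as.numeric(a_an))
  )
}

#' Run the full analysis over a cohort
#'
#' Reproduces every stage of the study analysis on in-memory cohort data:
#' the cardiac-phase manipulation check and group-level angles (when
#' recordings are supplied), the paired estimation and gamma-GEE analyses
#' of dominance durations, the discrimination mixture model with
#' binomial comparison, and the awareness-controlled GEE re-run on the
#' subjects screened as at-chance.
#'
#' @param cohort A list with elements `dominance` (dominance table),
#'   `discrimination` (data.frame `subject`, `k`, `n`) and optionally
#'   `recordings` (named list of [ecg_record()]), e.g. from
#'   [read_bids_cohort()].
#' @param sched_cfg A [scheduler_config()] for replaying recordings.
#' @param n_boot Bootstrap replicates for the paired and circular
#'   analyses.
#' @param n_draws Posterior draws for the mixture model.
#' @param threshold At-chance screening threshold on the membership
#'   probability.
#' @param seed Integer root seed.
#' @return A list: `manipulation`, `group_angles` (in-/anti-phase
#'   `circular_summary`s), `paired`, `gee`, `mixture`, `binomial`,
#'   `screen`, `gee_at_chance`.
#' @export
analyze_cohort <- function(cohort, sched_cfg = scheduler_config(),
                           n_boot = 10000, n_draws = 10000,
                           threshold = 0.05, seed = 1) {
  out <- list()
  if (!is.null(cohort$recordings) && length(cohort$recordings) >= 2L) {
    ids <- sort(names(cohort$recordings))
    ang <- lapply(ids, function(id) {
      a <- subject_pulse_angles(cohort$recordings[[id]], sched_cfg)
      if (nrow(a)) cbind(subject = id, a) else NULL
    })
    angles <- do.call(rbind, ang)
    out$manipulation <- manipulation_check(angles, n_boot = n_boot,
                                           seed = substream_seed(seed, 1L))
    split_by <- function(stim) {
      sub <- angles[angles$stimulus == stim, ]
      split(sub$angle, sub$subject)
    }
    out$group_angles <- list(
      inphase = group_bootstrap(split_by("inphase"), n_boot = n_boot,
                                seed = substream_seed(seed, 2L)),
      antiphase = group_bootstrap(split_by("antiphase"), n_boot = n_boot,
                                  seed = substream_seed(seed, 3L))
    )
  }
  if (!is.null(cohort$dominance)) {
    out$paired <- paired_bootstrap(cohort$dominance, n_boot = n_boot,
                                   seed = substream_seed(seed, 4L))
    out$gee <- fit_gamma_gee(cohort$dominance)
  }
  if (!is.null(cohort$discrimination)) {
    disc <- cohort$discrimination
    out$mixture <- fit_mixture(disc, n_draws = n_draws,
                               seed = substream_seed(seed, 5L))
    out$binomial <- binomial_above_chance(disc$k, disc$n[1L])
    out$screen <- screen_at_chance(disc, out$mixture, threshold = threshold)
    if (!is.null(cohort$dominance)) {
      keep <- cohort$dominance$subject %in% out$screen$retained
      if (length(unique(cohort$dominance$subject[keep])) >= 2L)
        out$gee_at_chance <- fit_gamma_gee(cohort$dominance[keep, , drop = FALSE])
    }
  }
  out
}
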