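# Cardiac angles and circular summaries. The cardiac cycle is mapped to
# the circle with the R-peak at +/- pi and the T-wave offset at 0, so
# systole occupies the negative half (-pi, 0) and diastole the positive
# half (0, pi). Subject- and group-level means come with percentile
# bootstrap CIs; the group level uses a hierarchical (random-effects)
# resampling scheme.

#' Map event times to cardiac angles
#'
#' For an event at time `t` inside beat `i` (`R_i <= t < R_{i+1}`) with
#' T-wave offset `T_i`: systolic events (`t < T_i`) map linearly onto
#' `[-pi, 0)` via `-pi + pi (t - R_i) / (T_i - R_i)`; diastolic events
#' (`t >= T_i`) map onto `[0, pi)` via `pi (t - T_i) / (R_{i+1} - T_i)`.
#' An event exactly at an R-peak gets `-pi` (start of systole; the same
#' point as `+pi` on the circle). Events outside the recording span or in
#' beats lacking a T-offset are dropped; the number dropped is reported in
#' the `n_dropped` attribute (with a warning for out-of-span events).
#'
#' @param event_times Event times in seconds.
#' @param events A [cardiac_events()] object.
#' @return Numeric vector of angles in `(-pi, pi]` (one per retained
#'   event) with attribute `n_dropped`.
#' @export
cardiac_angle <- function(event_times, events) {
  stopifnot(inherits(events, "cardiac_events"))
  r <- events$r_times
  tt <- events$t_offsets
  n <- length(r)
  out_of_span <- event_times < r[1L] | event_times > r[n]
  if (any(out_of_span))
    warning(sprintf("%d event(s) outside the recording span dropped",
                    sum(out_of_span)), call. = FALSE)
  t_in <- event_times[!out_of_span]
  beat <- findInterval(t_in, r)          # R_beat <= t < R_{beat+1}
  at_last_r <- beat == n                  # t == r[n] exactly
  angle <- rep(NA_real_, length(t_in))
  angle[at_last_r] <- -pi
  i <- which(!at_last_r)
  b <- beat[i]
  has_t <- !is.na(tt[b])
  i <- i[has_t]; b <- b[has_t]
  ti <- t_in[i]
  sys <- ti < tt[b]
  angle[i[sys]] <- -pi + pi * (ti[sys] - r[b[sys]]) / (tt[b[sys]] - r[b[sys]])
  dia <- !sys
  angle[i[dia]] <- pi * (ti[dia] - tt[b[dia]]) / (r[b[dia] + 1L] - tt[b[dia]])
  dropped <- sum(out_of_span) + sum(is.na(angle))
  res <- wrap_angle(angle[!is.na(angle)])
  attr(res, "n_dropped") <- dropped
  res
}

#' Circular mean
#'
#' Direction of the mean resultant vector, returned in `(-pi, pi]`.
#' Errors if the resultant length is (numerically) zero, in which case
#' the mean direction is undefined.
#'
#' @param angles Numeric vector of angles in radians (nonempty).
#' @return The mean angle in radians.
#' @export
circular_mean <- function(angles) {
  if (length(angles) == 0L) stop("`angles` must be nonempty", call. = FALSE)
  c_ <- mean(cos(angles)); s_ <- mean(sin(angles))
  if (sqrt(c_^2 + s_^2) < 1e-12)
    stop("circular mean undefined: zero resultant length", call. = FALSE)
  wrap_angle(atan2(s_, c_))
}

# Circular percentile CI: quantiles of replicate deviations from the
# point estimate, unwrapped to (-pi, pi], added back to the estimate.
# Endpoints may fall outside (-pi, pi] so that ci_low <= mean <= ci_high
# always holds on the arc selected by the bootstrap distribution.
circ_percentile_ci <- function(boot_means, point, probs = c(0.025, 0.975)) {
  dev <- wrap_angle(boot_means - point)
  point + stats::quantile(dev, probs, names = FALSE, type = 7)
}

#' Subject-level circular bootstrap
#'
#' Resamples the angles with replacement `n_boot` times and computes the
#' circular mean of each replicate. The point estimate is the circular
#' mean of the data; the CI is formed from the 2.5/97.5 percentiles of
#' the replicate deviations around the point estimate (so it cannot be
#' broken by wrap-around for means near +/- pi).
#'
#' @param angles Numeric vector of at least 2 angles (radians).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @param conf Confidence level.
#' @return A list of class `circular_summary`: `mean_angle`, `ci_low`,
#'   `ci_high`, `n`, `n_boot`.
#' @export
subject_bootstrap <- function(angles, n_boot = 10000, seed = NULL,
                              conf = 0.95) {
  if (length(angles) < 2L) stop("need at least 2 angles", call. = FALSE)
  point <- circular_mean(angles)
  bm <- with_seed(seed, boot_circ_means(angles, n_boot))
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  ci <- circ_percentile_ci(bm, point, probs)
  structure(list(mean_angle = point, ci_low = ci[1L], ci_high = ci[2L],
                 n = length(angles), n_boot = n_boot),
            class = "circular_summary")
}

# n_boot resampled circular means, chunked to bound memory.
boot_circ_means <- function(angles, n_boot, chunk = 2000L) {
  n <- length(angles)
  cs <- cos(angles); sn <- sin(angles)
  out <- numeric(n_boot)
  done <- 0L
  while (done < n_boot) {
    b <- min(chunk, n_boot - done)
    idx <- matrix(sample.int(n, n * b, replace = TRUE), nrow = n)
    out[done + seq_len(b)] <- atan2(colMeans(matrix(sn[idx], nrow = n)),
                                    colMeans(matrix(cs[idx], nrow = n)))
    done <- done + b
  }
  wrap_angle(out)
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("<circular_summary> mean %.3f rad, %d%% CI [%.3f, %.3f] (n = %d, %d boots)\n",
              x$mean_angle, 95L, x$ci_low, x$ci_high, x$n, x$n_boot))
  invisible(x)
}

#' Group-level random-effects circular bootstrap
#'
#' Hierarchical scheme accounting for both the population sampling
#' distribution and the within-subject sampling distribution: each
#' replicate resamples subjects with replacement, then resamples each
#' chosen subject's angles with replacement, takes per-subject circular
#' means, and finally their (unweighted) group circular mean. The point
#' estimate is the group circular mean of the subjects' circular means.
#' Subjects are canonicalized by sorting their names and each subject's
#' within-subject resampling runs on its own substream of `seed`, so the
#' result is invariant to the ordering of `per_subject_angles`.
#'
#' @param per_subject_angles Named list of angle vectors, one per subject
#'   (at least 2 subjects).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @param conf Confidence level.
#' @return A `circular_summary` (as [subject_bootstrap()]), with `n` the
#'   number of subjects.
#' @export
group_bootstrap <- function(per_subject_angles, n_boot = 10000, seed = NULL,
                            conf = 0.95) {
  ns <- length(per_subject_angles)
  if (ns < 2L) stop("need at least 2 subjects", call. = FALSE)
  nm <- names(per_subject_angles) %||% sprintf("s%03d", seq_len(ns))
  ord <- order(nm)
  per_subject_angles <- per_subject_angles[ord]
  subj_means <- vapply(per_subject_angles, circular_mean, numeric(1))
  point <- circular_mean(subj_means)
  # per-subject pools of resampled means (independent substreams)
  pools <- matrix(NA_real_, nrow = ns, ncol = n_boot)
  for (i in seq_len(ns)) {
    a <- per_subject_angles[[i]]
    pools[i, ] <- if (length(a) == 1L) rep(wrap_angle(a), n_boot)
    else with_seed(if (is.null(seed)) NULL else substream_seed(seed, i),
                   boot_circ_means(a, n_boot))
  }
  bm <- with_seed(if (is.null(seed)) NULL else substream_seed(seed, 0L), {
    subj_idx <- matrix(sample.int(ns, ns * n_boot, replace = TRUE), nrow = ns)
    col_idx <- matrix(sample.int(n_boot, ns * n_boot, replace = TRUE), nrow = ns)
    vals <- matrix(pools[cbind(as.vector(subj_idx), as.vector(col_idx))],
                   nrow = ns)
    wrap_angle(atan2(colMeans(sin(vals)), colMeans(cos(vals))))
  })
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  ci <- circ_percentile_ci(bm, point, probs)
  structure(list(mean_angle = point, ci_low = ci[1L], ci_high = ci[2L],
                 n = ns, n_boot = n_boot),
            class = "circular_summary")
}

#' Cardiac-phase manipulation check
#'
#' Verifies, per subject, that the in-phase stimulus pulses peaked in
#' systole (negative bootstrap mean cardiac angle) and the anti-phase
#' stimulus in diastole (positive mean angle). The check passes only if
#' every complete subject satisfies both signs; subjects missing one of
#' the two stimulus streams are flagged incomplete and do not enter the
#' pass decision.
#'
#' @param angles A data.frame with columns `subject`, `stimulus`
#'   (`"inphase"` / `"antiphase"`), `angle` (radians).
#' @param n_boot Bootstrap replicates per subject and stimulus.
#' @param seed Optional integer root seed.
#' @return A list with `table` (per subject: mean angles, CIs and sign
#'   flags), `pass` (logical), `incomplete` (character vector of subject
#'   ids).
#' @export
manipulation_check <- function(angles, n_boot = 10000, seed = NULL) {
  stopifnot(all(c("subject", "stimulus", "angle") %in% names(angles)))
  subjects <- sort(unique(angles$subject))
  rows <- list()
  incomplete <- character(0)
  for (si in seq_along(subjects)) {
    sub <- subjects[si]
    a_in <- angles$angle[angles$subject == sub & angles$stimulus == "inphase"]
    a_an <- angles$angle[angles$subject == sub & angles$stimulus == "antiphase"]
    if (length(a_in) < 2L || length(a_an) < 2L) {
      incomplete <- c(incomplete, sub)
      next
    }
    bi <- subject_bootstrap(a_in, n_boot,
                            seed = if (is.null(seed)) NULL else substream_seed(seed, 2L * si))
    ba <- subject_bootstrap(a_an, n_boot,
                            seed = if (is.null(seed)) NULL else substream_seed(seed, 2L * si + 1L))
    rows[[sub]] <- data.frame(
      subject = sub,
      inphase_mean = bi$mean_angle, inphase_lo = bi$ci_low, inphase_hi = bi$ci_high,
      antiphase_mean = ba$mean_angle, antiphase_lo = ba$ci_low, antiphase_hi = ba$ci_high,
      inphase_systolic = bi$mean_angle < 0,
      antiphase_diastolic = ba$mean_angle > 0,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  pass <- !is.null(tab) && nrow(tab) > 0 &&
    all(tab$inphase_systolic) && all(tab$antiphase_diastolic)
  list(table = tab, pass = pass, incomplete = incomplete)
}
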