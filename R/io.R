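# Plain-text interchange: BIDS-style physio TSV (+ JSON sidecar) for ECG,
# events TSV for dominance intervals, pulses and discrimination trials,
# YAML for cohort configurations.

#' Write / read an ECG recording as BIDS-style physio TSV
#'
#' The TSV holds a single `ecg` column (no time column); sampling rate
#' and start time live in the JSON sidecar (`SamplingFrequency`,
#' `StartTime`), as in BIDS physiological recordings. A `.gz` path is
#' compressed transparently.
#'
#' @param record An [ecg_record()].
#' @param path Path to the TSV (or TSV.gz) file; the sidecar replaces the
#'   extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_ecg_tsv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.table(data.frame(ecg = record$samples), con,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  side <- sub("\\.tsv(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(SamplingFrequency = record$fs, StartTime = record$start_time,
         Columns = list("ecg")),
    side, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_ecg_tsv
#' @export
read_ecg_tsv <- function(path) {
  side <- sub("\\.tsv(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(side)
  x <- utils::read.table(path, header = TRUE, sep = "\t")
  ecg_record(x$ecg, fs = as.numeric(meta$SamplingFrequency),
             start_time = as.numeric(meta$StartTime %||% 0))
}

#' Write a simulated cohort as a BIDS-like directory tree
#'
#' Generates and writes, per subject: `sub-XX/ecg.tsv.gz` with JSON
#' sidecar (one rivalry session's ECG), `sub-XX/task-rivalry_events.tsv`
#' (columns `onset`, `duration`, `eye`, `condition`, `block`, `censored`)
#' and `sub-XX/task-discrim_events.tsv` (columns `trial`, `correct`),
#' plus the generating configuration as `cohort.yaml` at the root. All
#' times are seconds relative to recording start.
#'
#' @param cfg A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @param seed Integer root seed.
#' @return `dir`, invisibly.
#' @export
write_bids_cohort <- function(cfg, dir, seed = 1) {
  stopifnot(inherits(cfg, "cohort_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "cohort.yaml"))
  riv <- simulate_rivalry_cohort(cfg, seed)
  dis <- simulate_discrimination(cfg, seed = substream_seed(seed, 90001L))
  mrr <- draw_subject_mean_rr(cfg, seed = substream_seed(seed, 90002L))
  for (i in seq_len(cfg$n_subjects)) {
    id <- sprintf("sub-%02d", i)
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE)
    rp <- simulate_rr_series(mrr[i], cfg$rr_sd,
                             cfg$n_blocks * cfg$block_duration,
                             seed = substream_seed(seed, 10000L + i))
    rec <- simulate_ecg(rp, seed = substream_seed(seed, 20000L + i))
    write_ecg_tsv(rec, file.path(sdir, "ecg.tsv.gz"))
    ev <- riv[riv$subject == id,
              c("onset", "duration", "eye", "condition", "block", "censored")]
    utils::write.table(ev, file.path(sdir, "task-rivalry_events.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    drow <- dis[dis$subject == id, ]
    dtab <- data.frame(
      trial = seq_len(drow$n),
      correct = as.integer(seq_len(drow$n) <= drow$k)
    )
    utils::write.table(dtab, file.path(sdir, "task-discrim_events.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a BIDS-like cohort directory
#'
#' Inverse of [write_bids_cohort()] (and compatible with any tree laid
#' out the same way): returns the recordings, the pooled dominance table,
#' and the per-subject discrimination counts.
#'
#' @param dir Cohort directory.
#' @return A list with `recordings` (named list of [ecg_record()]),
#'   `dominance` (data.frame), `discrimination` (data.frame with
#'   `subject`, `k`, `n`), and `config` (list, if `cohort.yaml` exists).
#' @export
read_bids_cohort <- function(dir) {
  subs <- sort(list.dirs(dir, recursive = FALSE))
  subs <- subs[grepl("sub-", basename(subs))]
  recordings <- list()
  dom <- list()
  dis <- list()
  for (s in subs) {
    id <- basename(s)
    ecg_path <- file.path(s, "ecg.tsv.gz")
    if (!file.exists(ecg_path)) ecg_path <- file.path(s, "ecg.tsv")
    if (file.exists(ecg_path)) recordings[[id]] <- read_ecg_tsv(ecg_path)
    rv <- file.path(s, "task-rivalry_events.tsv")
    if (file.exists(rv)) {
      tab <- utils::read.table(rv, header = TRUE, sep = "\t")
      tab$subject <- id
      dom[[id]] <- tab
    }
    dc <- file.path(s, "task-discrim_events.tsv")
    if (file.exists(dc)) {
      tab <- utils::read.table(dc, header = TRUE, sep = "\t")
      dis[[id]] <- data.frame(subject = id, k = sum(tab$correct),
                              n = nrow(tab))
    }
  }
  cfg_path <- file.path(dir, "cohort.yaml")
  list(
    recordings = recordings,
    dominance = if (length(dom)) do.call(rbind, c(dom, list(make.row.names = FALSE))) else NULL,
    discrimination = if (length(dis)) do.call(rbind, c(dis, list(make.row.names = FALSE))) else NULL,
    config = if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  )
}

#' Write a pulse schedule as events TSV
#'
#' Long format: one row per pulse event, columns `time_s`, `stimulus`
#' (`inphase`/`antiphase`) and `kind` (`commanded`/`display`).
#'
#' @param schedule A `pulse_schedule` from [replay_session()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_schedule_tsv <- function(schedule, path) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  long <- rbind(
    data.frame(time_s = schedule$inphase$commanded, stimulus = "inphase",
               kind = "commanded"),
    data.frame(time_s = schedule$inphase$display, stimulus = "inphase",
               kind = "display"),
    data.frame(time_s = schedule$antiphase$commanded, stimulus = "antiphase",
               kind = "commanded"),
    data.frame(time_s = schedule$antiphase$display, stimulus = "antiphase",
               kind = "display")
  )
  long <- long[order(long$time_s), ]
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
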