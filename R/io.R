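#' Write a cohort to delimited files
#'
#' One tab-separated signal matrix per participant (samples x channels,
#' header row of channel labels, file `<id>_signal.tsv`), plus
#' `participants.tsv` (participant_id, group, age, gender, n_trials) and
#' `events.tsv` (participant_id, trial_index, onset_sample, condition,
#' group, age, gender). Sampling rate goes into `paradigm.tsv` together
#' with the trial timing.
#'
#' @param cohort list with `recordings` and `participants`.
#' @param dir output directory (created if needed).
#' @param paradigm the [paradigm_spec()] used.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, paradigm) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pt <- cohort$participants
  write.table(pt, file.path(dir, "participants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ev_all <- list()
  for (i in seq_len(nrow(pt))) {
    id <- pt$participant_id[i]
    rec <- cohort$recordings[[id]]
    sig <- t(rec$signal)
    colnames(sig) <- rec$channel_labels
    write.table(format(sig, digits = 7, trim = TRUE, scientific = FALSE),
                file.path(dir, paste0(id, "_signal.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ev_all[[i]] <- data.frame(participant_id = id, rec$events[,
                              c("trial_index", "onset_sample", "condition")],
                              group = pt$group[i], age = pt$age[i],
                              gender = pt$gender[i])
  }
  write.table(do.call(rbind, ev_all), file.path(dir, "events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  par_df <- data.frame(field = c("sampling_rate", "trial_length",
                                 "cue_onset", "cue_offset", "mi_start",
                                 "mi_end"),
                       value = c(paradigm$sampling_rate,
                                 paradigm$trial_length, paradigm$cue_onset,
                                 paradigm$cue_offset, paradigm$mi_window))
  write.table(par_df, file.path(dir, "paradigm.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `participants.tsv`, `events.tsv`,
#'   `paradigm.tsv` and the per-participant signal matrices.
#' @return list with `recordings`, `participants` and `paradigm`.
#' @export
read_cohort <- function(dir) {
  pt <- read.table(file.path(dir, "participants.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  ev <- read.table(file.path(dir, "events.tsv"), header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  pr <- read.table(file.path(dir, "paradigm.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  getv <- function(f) pr$value[match(f, pr$field)]
  paradigm <- paradigm_spec(trial_length = getv("trial_length"),
                            cue_onset = getv("cue_onset"),
                            cue_offset = getv("cue_offset"),
                            mi_window = c(getv("mi_start"), getv("mi_end")),
                            sampling_rate = getv("sampling_rate"))
  recordings <- list()
  for (i in seq_len(nrow(pt))) {
    id <- pt$participant_id[i]
    sig <- as.matrix(read.table(file.path(dir, paste0(id, "_signal.tsv")),
                                header = TRUE, sep = "\t",
                                check.names = FALSE))
    events <- ev[ev$participant_id == id,
                 c("onset_sample", "condition", "trial_index")]
    recordings[[id]] <- eeg_recording(t(sig), colnames(sig),
                                      paradigm$sampling_rate, events,
                                      participant = list(
                                        id = id, group = pt$group[i],
                                        age = pt$age[i],
                                        gender = pt$gender[i]))
  }
  list(recordings = recordings, participants = pt, paradigm = paradigm)
}

#' Read a flat key-value configuration file
#'
#' TOML-style `key = value` lines (comments with `#`). Per-band values use
#' dotted keys, e.g. `group_a.erd_depth.alpha = 0.5`.
#'
#' @param path file path.
#' @return named list of values (numeric where possible).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stopf("bad config line: %s", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else gsub("^\"|\"$", "", val)
  }
  out
}
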