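#' Write / read an EEG recording as delimited text with a JSON sidecar
#'
#' The signal matrix is stored as CSV (one row per channel, first column
#' the 10-20 label) and the sampling rate plus stimulation schedule in a
#' JSON sidecar next to it (`<path>.json`).
#'
#' @param recording An [eeg_recording()].
#' @param path CSV file path.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns an [eeg_recording()].
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  df <- data.frame(channel = recording$channel_labels,
                   recording$signal, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(sampling_rate = recording$sampling_rate)
  if (!is.null(recording$schedule)) {
    meta$schedule <- list(
      blocks = recording$schedule$blocks,
      rest_blocks = recording$schedule$rest_blocks,
      total_duration = recording$schedule$total_duration)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- df$channel
  sig <- as.matrix(df[, -1, drop = FALSE])
  dimnames(sig) <- list(labels, NULL)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  schedule <- NULL
  if (!is.null(meta$schedule)) {
    schedule <- structure(
      list(blocks = as.data.frame(meta$schedule$blocks),
           rest_blocks = as.data.frame(meta$schedule$rest_blocks),
           total_duration = meta$schedule$total_duration),
      class = "stim_schedule")
  }
  eeg_recording(sig, labels, meta$sampling_rate, schedule)
}

#' Write / read a virtual-kiosk session log as a CSV triplet
#'
#' Stores `gaze.csv` (`time,x,y,z,aoi`), `hand.csv` (`time,x,y,z`) and
#' `events.csv` (`time,step_id,is_error`) in `dir`.
#'
#' @param log A [vr_session_log()].
#' @param dir Directory (created if needed).
#' @return `write_vr_session` returns `dir` invisibly; `read_vr_session`
#'   returns a [vr_session_log()].
#' @export
write_vr_session <- function(log, dir) {
  stopifnot(inherits(log, "vr_session_log"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(log$gaze, file.path(dir, "gaze.csv"), row.names = FALSE)
  utils::write.csv(log$hand, file.path(dir, "hand.csv"), row.names = FALSE)
  utils::write.csv(log$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_vr_session
#' @export
read_vr_session <- function(dir) {
  vr_session_log(
    gaze = utils::read.csv(file.path(dir, "gaze.csv")),
    hand = utils::read.csv(file.path(dir, "hand.csv")),
    events = utils::read.csv(file.path(dir, "events.csv"))
  )
}

#' Write / read a cohort specification as a YAML config file
#'
#' Serializes the generator configuration — group sizes, per-feature
#' marginal parameters per group, cross-modal correlation targets and
#' seed — as nested key-value YAML.
#'
#' @param spec A [cohort_spec()].
#' @param path YAML file path.
#' @return `write_cohort_spec` returns `path` invisibly;
#'   `read_cohort_spec` returns a [cohort_spec()].
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  as_rows <- function(df) if (is.null(df)) NULL else unname(
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, ])))
  yaml::write_yaml(list(
    n_per_group = spec$n_per_group,
    seed = spec$seed,
    behavioral = as_rows(spec$behavioral),
    neurological = as_rows(spec$neurological),
    cross_modal = as_rows(spec$cross_modal)), path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  from_rows <- function(rows) {
    if (is.null(rows)) return(NULL)
    do.call(rbind, lapply(rows, function(r) {
      as.data.frame(lapply(r, function(v) {
        if (identical(v, ".inf")) Inf else if (identical(v, "-.inf")) {
          -Inf
        } else v
      }))
    }))
  }
  cohort_spec(n_per_group = y$n_per_group,
              behavioral = from_rows(y$behavioral),
              neurological = from_rows(y$neurological),
              cross_modal = from_rows(y$cross_modal),
              seed = y$seed)
}

#' Write / read a subjects-by-features table as CSV
#'
#' Header row preserved verbatim (feature names may contain Greek band
#' letters); `group` restored as a factor with levels `hc`, `amci`.
#'
#' @param table Feature table (e.g. from [simulate_cohort()]).
#' @param path CSV file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the data frame.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if ("group" %in% names(tab)) {
    tab$group <- factor(tab$group, levels = c("hc", "amci"))
  }
  tab
}
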