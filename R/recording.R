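#' Construct an EEG recording object
#'
#' Container for a multichannel EEG signal with its 10-20 channel labels,
#' sampling rate and attached stimulation schedule.
#'
#' @param signal Numeric matrix, channels x samples (microvolts). Row names,
#'   if present, must agree with `channel_labels`.
#' @param channel_labels Character vector of 10-20 labels; must be exactly
#'   the 19-channel montage.
#' @param sampling_rate Sampling rate in Hz (default 200).
#' @param schedule A `stim_schedule`, or `NULL`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, channel_labels = rownames(signal),
                          sampling_rate = 200, schedule = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("signal must be a numeric matrix (channels x samples)",
         call. = FALSE)
  }
  assert_montage(channel_labels)
  if (nrow(signal) != length(channel_labels)) {
    stop("nrow(signal) must equal length(channel_labels)", call. = FALSE)
  }
  rownames(signal) <- channel_labels
  if (!is.null(schedule)) {
    expected <- round(schedule$total_duration * sampling_rate)
    if (ncol(signal) != expected) {
      stop("sample count (", ncol(signal), ") does not match schedule ",
           "duration x sampling rate (", expected, ")", call. = FALSE)
    }
  }
  structure(
    list(signal = signal, channel_labels = channel_labels,
         sampling_rate = sampling_rate, schedule = schedule),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$signal), " channels x ", ncol(x$signal),
      " samples @ ", x$sampling_rate, " Hz (",
      ncol(x$signal) / x$sampling_rate, " s)\n", sep = "")
  invisible(x)
}

# Column index range of a time interval [from, to) in seconds.
sample_range <- function(from, to, sampling_rate) {
  lo <- floor(from * sampling_rate) + 1L
  hi <- floor(to * sampling_rate)
  seq.int(lo, hi)
}

# Evaluate expr with the RNG seeded locally; global .Random.seed restored.
with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("seed is required", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
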