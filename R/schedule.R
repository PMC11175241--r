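#' Build an intermittent photic stimulation (IPS) schedule
#'
#' Constructs the block layout of an IPS session: one stimulation block per
#' requested frequency, in the given order, each followed by a rest block.
#' The canonical session flashes at 3, 5, 10, 12, 15 and 20 Hz in 10 s
#' blocks alternating with 10 s rest, for a 120 s session.
#'
#' @param frequencies Numeric vector of stimulation frequencies (Hz),
#'   non-empty.
#' @param stim_dur Duration of each stimulation block (s), `>= 0`.
#' @param rest_dur Duration of each rest block (s), `>= 0`. A zero rest
#'   duration produces no rest blocks.
#' @return An object of class `stim_schedule`: list with `blocks` (data
#'   frame `frequency`, `onset`, `offset`), `rest_blocks` (data frame
#'   `onset`, `offset`) and `total_duration` (s).
#' @examples
#' sched <- make_ips_schedule()
#' sched$total_duration  # 120
#' @export
make_ips_schedule <- function(frequencies = IPS_FREQUENCIES,
                              stim_dur = 10, rest_dur = 10) {
  if (length(frequencies) == 0L) {
    stop("frequencies must be non-empty", call. = FALSE)
  }
  if (stim_dur < 0 || rest_dur < 0) {
    stop("durations must be >= 0", call. = FALSE)
  }
  n <- length(frequencies)
  cycle <- stim_dur + rest_dur
  onset <- (seq_len(n) - 1) * cycle
  blocks <- data.frame(
    frequency = as.numeric(frequencies),
    onset = onset,
    offset = onset + stim_dur
  )
  if (rest_dur > 0) {
    rest_blocks <- data.frame(onset = onset + stim_dur,
                              offset = onset + cycle)
  } else {
    rest_blocks <- data.frame(onset = numeric(0), offset = numeric(0))
  }
  structure(
    list(blocks = blocks, rest_blocks = rest_blocks,
         total_duration = n * cycle),
    class = "stim_schedule"
  )
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat("<stim_schedule> ", nrow(x$blocks), " stimulation block(s), ",
      x$total_duration, " s total\n", sep = "")
  print(x$blocks)
  invisible(x)
}

# Block row for stimulation frequency f; errors if absent.
schedule_block <- function(schedule, f) {
  i <- which(schedule$blocks$frequency == f)
  if (length(i) == 0L) {
    stop("frequency ", f, " Hz not in schedule", call. = FALSE)
  }
  schedule$blocks[i[1L], ]
}
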