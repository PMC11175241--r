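#' Construct a virtual-kiosk session log
#'
#' Bundles the three streams recorded during one virtual-kiosk session:
#' 3-D gaze samples with area-of-interest (AOI) labels, 3-D hand-controller
#' samples, and step/error events for the six kiosk steps (choose venue,
#' burger, side, drink, payment, password).
#'
#' @param gaze Data frame `time, x, y, z, aoi`; `aoi` one of `"target"`,
#'   `"nontarget"`, `"none"`. Missing coordinates (blinks) are allowed as
#'   `NA`.
#' @param hand Data frame `time, x, y, z`.
#' @param events Data frame `time, step_id, is_error`; `step_id` in 1..6.
#'   The final event must be a non-error step-6 record (task completion).
#' @return An object of class `vr_session_log`.
#' @export
vr_session_log <- function(gaze, hand, events) {
  for (nm in c("time", "x", "y", "z", "aoi")) {
    if (!nm %in% names(gaze)) stop("gaze lacks column ", nm, call. = FALSE)
  }
  for (nm in c("time", "x", "y", "z")) {
    if (!nm %in% names(hand)) stop("hand lacks column ", nm, call. = FALSE)
  }
  for (nm in c("time", "step_id", "is_error")) {
    if (!nm %in% names(events)) {
      stop("events lacks column ", nm, call. = FALSE)
    }
  }
  if (nrow(events) == 0L) stop("events stream is empty", call. = FALSE)
  for (s in list(gaze$time, hand$time, events$time)) {
    if (length(s) > 1L && any(diff(s) < 0)) {
      stop("timestamps must be non-decreasing within each stream",
           call. = FALSE)
    }
  }
  if (!all(events$step_id %in% 1:6)) {
    stop("step_id must be one of the six kiosk steps (1..6)", call. = FALSE)
  }
  last <- events[nrow(events), ]
  if (last$step_id != 6L || isTRUE(last$is_error)) {
    stop("session must end with a step-6 completion event", call. = FALSE)
  }
  structure(list(gaze = gaze, hand = hand, events = events),
            class = "vr_session_log")
}

path_length <- function(df) {
  ok <- stats::complete.cases(df[, c("x", "y", "z")])
  p <- as.matrix(df[ok, c("x", "y", "z")])
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Extract the six virtual-kiosk behavioral features
#'
#' Computes, from one session log: scanpath length (cumulative Euclidean
#' gaze travel, m), proportion of fixation duration (% of menu-item dwell
#' time spent on the target item), hand movement distance (m), hand
#' movement speed (m/s), time to completion (s) and the number of errors.
#'
#' Dwell time is sample-wise: each gaze sample's AOI label owns the
#' interval up to the next sample. Gaze samples with missing coordinates
#' (blinks) are dropped from the scanpath; samples with `aoi = "none"` are
#' excluded from both terms of the fixation proportion. Hand speed is hand
#' distance divided by time to completion; with
#' `speed_excludes_stationary = TRUE` the denominator instead sums only
#' inter-sample intervals where the hand moved faster than 0.01 m/s.
#'
#' @param log A [vr_session_log()].
#' @param speed_excludes_stationary Logical; see above. Default `FALSE`.
#' @return A one-row data frame with columns `scanpath_length`,
#'   `fixation_proportion`, `hand_distance`, `hand_speed`,
#'   `time_to_completion`, `n_errors`.
#' @export
extract_behavioral_features <- function(log,
                                        speed_excludes_stationary = FALSE) {
  stopifnot(inherits(log, "vr_session_log"))
  if (nrow(log$gaze) == 0L || nrow(log$hand) == 0L) {
    stop("gaze and hand streams must be non-empty", call. = FALSE)
  }
  ev <- log$events
  done <- ev$time[ev$step_id == 6L & !ev$is_error]
  if (length(done) == 0L) {
    stop("no step-6 completion event in log", call. = FALSE)
  }
  t0 <- min(ev$time)
  time_to_completion <- max(done) - t0
  n_errors <- sum(ev$is_error)

  scanpath_length <- path_length(log$gaze)
  hand_distance <- path_length(log$hand)

  # sample-wise AOI dwell: interval after each sample belongs to its label
  g <- log$gaze
  dt <- c(diff(g$time), 0)
  t_target <- sum(dt[g$aoi == "target"], na.rm = TRUE)
  t_menu <- sum(dt[g$aoi %in% c("target", "nontarget")], na.rm = TRUE)
  fixation_proportion <- if (t_menu > 0) 100 * t_target / t_menu else NA_real_

  if (speed_excludes_stationary) {
    h <- log$hand
    ok <- stats::complete.cases(h[, c("x", "y", "z")])
    p <- as.matrix(h[ok, c("x", "y", "z")])
    th <- h$time[ok]
    seg <- sqrt(rowSums(diff(p)^2))
    dth <- diff(th)
    moving <- dth > 0 & seg / dth > 0.01
    active <- sum(dth[moving])
    hand_speed <- if (active > 0) sum(seg[moving]) / active else 0
  } else {
    hand_speed <- if (time_to_completion > 0) {
      hand_distance / time_to_completion
    } else NA_real_
  }

  data.frame(scanpath_length = scanpath_length,
             fixation_proportion = fixation_proportion,
             hand_distance = hand_distance,
             hand_speed = hand_speed,
             time_to_completion = time_to_completion,
             n_errors = n_errors)
}

BEHAVIORAL_FEATURES <- c("scanpath_length", "fixation_proportion",
                         "hand_distance", "hand_speed",
                         "time_to_completion", "n_errors")
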