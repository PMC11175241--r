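# Random 3-D walk with n points and total path length L, starting at the
# origin: equal-length steps in uniformly random directions.
random_walk3 <- function(n, L) {
  if (n < 2L || L <= 0) {
    return(matrix(0, max(n, 1L), 3))
  }
  step <- L / (n - 1)
  v <- matrix(rnorm(3 * (n - 1)), ncol = 3)
  v <- v / sqrt(rowSums(v^2)) * step
  rbind(c(0, 0, 0), apply(v, 2, cumsum))
}

#' Simulate one virtual-kiosk session log
#'
#' Constructs a session whose extracted behavioral features match the
#' requested targets: the gaze and hand streams are random walks with the
#' requested total path lengths, AOI labels are allocated so the target
#' dwell share among menu samples equals the requested fixation
#' proportion, step-completion events partition the requested duration,
#' and error events are placed uniformly. Hand speed is emergent
#' (`hand_distance / time_to_completion`); supply `hand_speed` instead of
#' `hand_distance` to fix it via the distance.
#'
#' @param params Named list with `time_to_completion` (s, > 0), `n_errors`
#'   (count), `scanpath_length` (m), `fixation_proportion` (\%), and one of
#'   `hand_distance` (m) or `hand_speed` (m/s).
#' @param seed Integer seed; required.
#' @param gaze_rate,hand_rate Sampling rates (Hz) of the synthesized gaze
#'   and hand streams. Default 50.
#' @param menu_fraction Fraction of gaze samples on menu items (target or
#'   non-target AOI); the remainder are labeled `"none"`. Default 0.8.
#' @return A [vr_session_log()].
#' @examples
#' log <- simulate_vr_session(list(time_to_completion = 60, n_errors = 2,
#'   scanpath_length = 30, fixation_proportion = 55, hand_distance = 12),
#'   seed = 7)
#' extract_behavioral_features(log)
#' @export
simulate_vr_session <- function(params, seed, gaze_rate = 50,
                                hand_rate = 50, menu_fraction = 0.8) {
  T <- params$time_to_completion
  if (is.null(T) || !is.finite(T) || T <= 0) {
    stop("time_to_completion must be positive", call. = FALSE)
  }
  n_err <- as.integer(params$n_errors %||% 0)
  if (n_err < 0) stop("n_errors must be >= 0", call. = FALSE)
  L_gaze <- params$scanpath_length %||% 0
  fix_p <- params$fixation_proportion %||% 50
  if (L_gaze < 0 || fix_p < 0 || fix_p > 100) {
    stop("infeasible behavioral parameters", call. = FALSE)
  }
  L_hand <- if (!is.null(params$hand_distance)) {
    params$hand_distance
  } else if (!is.null(params$hand_speed)) {
    params$hand_speed * T
  } else 0
  if (L_hand < 0) stop("hand distance must be >= 0", call. = FALSE)

  with_seed(seed, {
    n_g <- max(2L, floor(T * gaze_rate) + 1L)
    n_h <- max(2L, floor(T * hand_rate) + 1L)
    t_g <- seq(0, T, length.out = n_g)
    t_h <- seq(0, T, length.out = n_h)

    gaze_xyz <- random_walk3(n_g, L_gaze)
    hand_xyz <- random_walk3(n_h, L_hand)

    # AOI labels: last (zero-dwell) sample is "none" so the time-weighted
    # proportion equals the count proportion among menu samples.
    aoi <- rep("none", n_g)
    pool <- seq_len(n_g - 1L)
    n_menu <- round(length(pool) * menu_fraction)
    menu_idx <- sort(sample(pool, n_menu))
    n_target <- round(n_menu * fix_p / 100)
    target_idx <- sort(sample(menu_idx, n_target))
    aoi[menu_idx] <- "nontarget"
    aoi[target_idx] <- "target"

    gaze <- data.frame(time = t_g, x = gaze_xyz[, 1], y = gaze_xyz[, 2],
                       z = gaze_xyz[, 3], aoi = aoi,
                       stringsAsFactors = FALSE)
    hand <- data.frame(time = t_h, x = hand_xyz[, 1], y = hand_xyz[, 2],
                       z = hand_xyz[, 3])

    # session-start marker, per-step completions, uniform error times
    steps <- data.frame(time = c(0, T * (1:6) / 6),
                        step_id = c(1L, 1:6),
                        is_error = FALSE)
    if (n_err > 0) {
      errs <- data.frame(time = sort(runif(n_err, 0, T * 0.99)),
                         step_id = sample(1:6, n_err, replace = TRUE),
                         is_error = TRUE)
      events <- rbind(steps, errs)
      events <- events[order(events$time, events$is_error), ]
    } else {
      events <- steps
    }
    rownames(events) <- NULL
    vr_session_log(gaze, hand, events)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
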