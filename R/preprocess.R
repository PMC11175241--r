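#' Remove per-channel mean
#'
#' Normalizes every channel to zero average, the first preprocessing step
#' before spectral or connectivity analysis.
#'
#' @param recording An [eeg_recording()].
#' @return The recording with each channel mean-centered.
#' @export
zero_mean <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (ncol(recording$signal) == 0L) stop("empty channel", call. = FALSE)
  recording$signal <- recording$signal - rowMeans(recording$signal)
  recording
}

# Threshold one segment: db4 DWT, zero detail/approximation coefficients
# whose magnitude exceeds the beta-scaled robust threshold, reconstruct.
threshold_segment <- function(x, beta, levels, k_factor = 4) {
  n <- length(x)
  target <- ceiling(n / 2^levels) * 2^levels
  pad <- target - n
  xp <- if (pad > 0) c(x, x[seq(n, n - pad + 1L)]) else x
  cf <- dwt_periodic(xp, levels)
  shrink <- function(d) {
    s <- median(abs(d)) / 0.6745
    if (s == 0) s <- sd(d)
    if (is.na(s) || s == 0) return(d)
    thr <- k_factor * s * (beta / 0.1)
    d[abs(d) > thr] <- 0
    d
  }
  cf$details <- lapply(cf$details, shrink)
  cf$approx <- shrink(cf$approx)
  idwt_periodic(cf)[seq_len(n)]
}

#' Wavelet-threshold artifact removal
#'
#' Automatic, tunable artifact attenuation: each channel is processed in
#' 1 s sliding windows with 50\% overlap; each window is decomposed with a
#' 5-level db4 discrete wavelet transform, coefficients whose magnitude
#' exceeds a data-adaptive robust threshold (median-absolute-deviation
#' scale times `4 * beta / 0.1`) are set to zero ("elimination"), and the
#' windows are Hann-weighted and overlap-added back together. Smaller
#' `beta` lowers the threshold and removes more aggressively; clean
#' bounded signals pass nearly unchanged at the default `beta = 0.1`.
#'
#' This is a self-contained simplified implementation of tunable
#' wavelet-threshold artifact removal; the operation is exposed behind
#' this one interface so a different artifact remover can be substituted.
#'
#' @param recording An [eeg_recording()].
#' @param wavelet Wavelet name; only `"db4"` is implemented.
#' @param beta Positive threshold-tuning scalar; default 0.1.
#' @param mode Removal mode; only `"elimination"` (zeroing) is implemented.
#' @param window_s Analysis window length in seconds (default 1).
#' @param levels Decomposition depth (default 5).
#' @return The recording with artifacts attenuated; shape and sampling
#'   rate preserved.
#' @export
remove_artifacts <- function(recording, wavelet = "db4", beta = 0.1,
                             mode = "elimination", window_s = 1,
                             levels = 5) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (wavelet != "db4") stop("unknown wavelet: ", wavelet, call. = FALSE)
  if (mode != "elimination") stop("unknown mode: ", mode, call. = FALSE)
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  fs <- recording$sampling_rate
  W <- round(fs * window_s)
  if (ncol(recording$signal) < W) {
    stop("signal shorter than one analysis window", call. = FALSE)
  }
  hop <- W %/% 2L
  n <- ncol(recording$signal)
  # periodic Hann: 50% overlapped windows sum to one in the interior
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(W) - 1) / W)

  clean <- recording$signal
  for (ch in seq_len(nrow(clean))) {
    x <- clean[ch, ]
    # reflect-pad half a window on each side so every original sample
    # sits in the unit-weight interior of the overlap-add
    n_starts <- ceiling((hop + n) / hop)
    np <- (n_starts - 1L) * hop + W
    tail_pad <- np - n - hop
    xp <- c(x[seq(hop, 1L)],
            x,
            x[seq(n, n - tail_pad + 1L)])
    acc <- numeric(np)
    wsum <- numeric(np)
    for (s in seq(1L, np - W + 1L, by = hop)) {
      idx <- s:(s + W - 1L)
      acc[idx] <- acc[idx] + threshold_segment(xp[idx], beta, levels) * w
      wsum[idx] <- wsum[idx] + w
    }
    keep <- hop + seq_len(n)
    clean[ch, ] <- acc[keep] / wsum[keep]
  }
  recording$signal <- clean
  recording
}
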