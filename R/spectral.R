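# Discrete prolate spheroidal sequences via the standard symmetric
# tridiagonal eigenproblem (Percival & Walden); W is the half-bandwidth
# as a fraction of the sampling rate. Unit-energy normalization.
dpss_tapers <- function(n, nw, k) {
  w <- nw / n
  t <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off_v <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(t + 1, t + 1)] <- diag_v
  A[cbind(1:(n - 1), 2:n)] <- off_v
  A[cbind(2:n, 1:(n - 1))] <- off_v
  e <- eigen(A, symmetric = TRUE)
  tapers <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tapers[, j] <- tapers[, j] / sqrt(sum(tapers[, j]^2))
    if (sum(tapers[, j]) < 0) tapers[, j] <- -tapers[, j]
  }
  tapers
}

.taper_cache <- new.env(parent = emptyenv())

get_tapers <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (is.null(.taper_cache[[key]])) {
    .taper_cache[[key]] <- dpss_tapers(n, nw, k)
  }
  .taper_cache[[key]]
}

#' Multitaper time-frequency decomposition
#'
#' Sliding-window spectral power of every channel: 500 ms windows, 1-50 Hz
#' at 1 Hz resolution. The default estimator averages three DPSS (Slepian)
#' tapers giving 8 Hz total frequency smoothing; `taper = "hann"` uses a
#' single Hann taper (plain windowed FFT) instead. Power is scaled so a
#' pure sinusoid of amplitude `a` at a bin frequency yields `a^2 / 2`
#' (its mean-square power) at that bin.
#'
#' @param recording An [eeg_recording()] (preprocessed).
#' @param window_s Window length in seconds (default 0.5).
#' @param hop_s Hop between window centers in seconds (default 0.1).
#' @param fmin,fmax Frequency range, Hz (defaults 1 and 50; 1 Hz steps).
#' @param taper `"dpss"` (3 tapers, 8 Hz smoothing) or `"hann"`.
#' @return An object of class `tf_map`: list with `power`
#'   (channel x frequency x time array, microvolt^2), `frequencies`,
#'   `times` (window centers, s), `channel_labels`, `time_step`.
#' @export
time_frequency <- function(recording, window_s = 0.5, hop_s = 0.1,
                           fmin = 1, fmax = 50, taper = c("dpss", "hann")) {
  stopifnot(inherits(recording, "eeg_recording"))
  taper <- match.arg(taper)
  fs <- recording$sampling_rate
  W <- round(window_s * fs)
  hop <- max(1L, round(hop_s * fs))
  n <- ncol(recording$signal)
  if (n < W) stop("recording shorter than one window", call. = FALSE)

  tapers <- if (taper == "dpss") {
    get_tapers(W, nw = 2, k = 3)        # NW = 2 -> 3 tapers, 8 Hz smoothing
  } else {
    h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(W) - 1) / W)
    matrix(h / sqrt(sum(h^2)), ncol = 1)
  }
  k <- ncol(tapers)
  # calibration so a bin-centered sinusoid of amplitude a reads a^2/2
  scale <- 2 / mean(colSums(tapers)^2)

  nfft <- fs                               # 1 Hz bins
  freqs <- seq(fmin, fmax)
  fbin <- freqs + 1L                       # fft bin index (DC = 1)
  starts <- seq(1L, n - W + 1L, by = hop)
  centers <- (starts - 1 + (W - 1) / 2) / fs
  n_ch <- nrow(recording$signal)

  power <- array(0, c(n_ch, length(freqs), length(starts)),
                 dimnames = list(recording$channel_labels, freqs, NULL))
  idx <- outer(seq_len(W) - 1L, starts, `+`)
  for (ch in seq_len(n_ch)) {
    segs <- matrix(recording$signal[ch, idx], W)
    acc <- 0
    for (j in seq_len(k)) {
      padded <- rbind(segs * tapers[, j], matrix(0, nfft - W, ncol(segs)))
      acc <- acc + Mod(stats::mvfft(padded)[fbin, , drop = FALSE])^2
    }
    power[ch, , ] <- acc / k * scale
  }
  structure(list(power = power, frequencies = freqs, times = centers,
                 time_step = hop / fs,
                 channel_labels = recording$channel_labels,
                 schedule = recording$schedule),
            class = "tf_map")
}

db <- function(p, floor_db = -120) {
  10 * log10(pmax(p, 10^(floor_db / 10)))
}

#' Harmonic SSVEP power for one electrode
#'
#' Mean spectral power at the n-th harmonic of the stimulation frequency
#' over the corresponding stimulation block, in dB. The first and last
#' `edge_s` seconds of the block are excluded (half-window edge effects).
#'
#' @param tf A `tf_map` from [time_frequency()].
#' @param schedule A `stim_schedule`; defaults to the one attached to `tf`.
#' @param electrode 10-20 channel label.
#' @param f Stimulation frequency (Hz); must be in the schedule.
#' @param n Harmonic number; `f * n` must be below 50 Hz.
#' @param edge_s Block-edge exclusion (s), default 0.25.
#' @param floor_db dB floor substituted for zero power, default -120.
#' @return Power in dB (scalar).
#' @export
harmonic_power <- function(tf, schedule = tf$schedule, electrode, f, n,
                           edge_s = 0.25, floor_db = -120) {
  stopifnot(inherits(tf, "tf_map"))
  if (f * n >= 50) {
    stop("harmonic frequency f*n = ", f * n, " is outside the 1-50 Hz ",
         "analysis range", call. = FALSE)
  }
  blk <- schedule_block(schedule, f)
  if (!electrode %in% tf$channel_labels) {
    stop("unknown electrode: ", electrode, call. = FALSE)
  }
  sel <- tf$times >= blk$onset + edge_s & tf$times <= blk$offset - edge_s
  if (!any(sel)) stop("no time bins inside the stimulation block",
                      call. = FALSE)
  fi <- match(f * n, tf$frequencies)
  if (is.na(fi)) stop("frequency ", f * n, " Hz not on the analysis grid",
                      call. = FALSE)
  db(mean(tf$power[electrode, fi, sel]), floor_db)
}

#' Harmonic power table over the full schedule
#'
#' Evaluates [harmonic_power()] for every electrode, every stimulation
#' frequency in the schedule, and every harmonic `n` with `f * n < 50`.
#'
#' @inheritParams harmonic_power
#' @return Data frame with columns `electrode`, `frequency`, `harmonic`,
#'   `power_db`.
#' @export
harmonic_power_table <- function(tf, schedule = tf$schedule,
                                 edge_s = 0.25, floor_db = -120) {
  rows <- list()
  for (f in schedule$blocks$frequency) {
    for (n in seq_len(floor(49.999 / f))) {
      if (f * n >= 50) break
      for (e in tf$channel_labels) {
        rows[[length(rows) + 1L]] <- data.frame(
          electrode = e, frequency = f, harmonic = n,
          power_db = harmonic_power(tf, schedule, e, f, n, edge_s,
                                    floor_db))
      }
    }
  }
  do.call(rbind, rows)
}

#' Lobe power: electrode-averaged harmonic power
#'
#' Averages harmonic power over the electrodes of one lobe. By default the
#' average is taken on the dB scale (the scale on which the published
#' parietal/occipital ratios near 0.7-0.8 are meaningful); `scale =
#' "linear"` averages linear power and converts afterwards.
#'
#' @param table Data frame from [harmonic_power_table()].
#' @param lobe A [lobe_set()].
#' @param f,n Stimulation frequency and harmonic.
#' @param scale `"db"` or `"linear"`.
#' @return Lobe power in dB (scalar).
#' @export
lobe_power <- function(table, lobe, f, n, scale = c("db", "linear")) {
  scale <- match.arg(scale)
  vals <- vapply(lobe$electrodes, function(e) {
    v <- table$power_db[table$electrode == e & table$frequency == f &
                          table$harmonic == n]
    if (length(v) != 1L) {
      stop("electrode ", e, " missing from table for f = ", f, ", n = ", n,
           call. = FALSE)
    }
    v
  }, numeric(1))
  if (scale == "db") mean(vals) else db(mean(10^(vals / 10)))
}

#' Lobe power ratio (parietal / occipital)
#'
#' The dorsal-stream response index: the ratio of parietal to occipital
#' lobe power (dB scale) at harmonic `n` of stimulation frequency `f`.
#'
#' @inheritParams lobe_power
#' @return Dimensionless ratio (scalar).
#' @export
lobe_power_ratio <- function(table, f, n, scale = "db") {
  lp_o <- lobe_power(table, lobe_set("occipital"), f, n, scale)
  if (lp_o == 0) stop("occipital lobe power is zero; ratio undefined",
                      call. = FALSE)
  lobe_power(table, lobe_set("parietal"), f, n, scale) / lp_o
}

#' Extract all lobe-power-ratio features from a recording
#'
#' Runs the full spectral pathway (time-frequency, harmonic power, lobe
#' averaging, parietal/occipital ratio) and returns one named feature per
#' (stimulation frequency, harmonic) pair with `f * n < 50`. Names follow
#' the `<f>PS-POR-<n>H` scheme, e.g. `12PS-POR-1H`.
#'
#' @param recording An [eeg_recording()] with a full schedule attached.
#' @param ... Passed to [time_frequency()].
#' @return Named numeric vector of lobe power ratios.
#' @export
extract_power_features <- function(recording, ...) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.null(recording$schedule)) {
    stop("recording has no stimulation schedule", call. = FALSE)
  }
  tf <- time_frequency(recording, ...)
  tab <- harmonic_power_table(tf)
  out <- numeric(0)
  for (f in recording$schedule$blocks$frequency) {
    for (n in seq_len(floor(49.999 / f))) {
      if (f * n >= 50) break
      out[sprintf("%gPS-POR-%dH", f, n)] <- lobe_power_ratio(tab, f, n)
    }
  }
  out
}

#' Amplitudes that plant a target lobe power ratio
#'
#' Chooses occipital and parietal sinusoid amplitudes so that, in a
#' noise-free recording, the spectral pipeline's dB lobe powers stand in
#' the requested ratio: the occipital amplitude is set to read `ref_db`
#' dB and the parietal amplitude to read `target_ratio * ref_db` dB. The
#' pipeline's dB response to unit amplitude is measured once on a
#' single-block calibration recording, which makes the planted ratio
#' exact up to floating point for the linear, noise-free pipeline.
#'
#' @param f Stimulation frequency (Hz).
#' @param n Harmonic number.
#' @param target_ratio Desired parietal/occipital dB-power ratio.
#' @param ref_db Occipital reference level in dB (default 20).
#' @param sampling_rate Hz, default 200.
#' @return An [amplitude_spec()] data frame with two rows.
#' @export
plant_lpr_amplitudes <- function(f, n = 1, target_ratio, ref_db = 20,
                                 sampling_rate = 200) {
  cal_sched <- make_ips_schedule(f, 10, 0)
  cal <- simulate_eeg(cal_sched, amplitude_spec(f, "occipital", n, 1),
                      noise = list(pink = 0, white = 0), seed = 1,
                      sampling_rate = sampling_rate)
  d1 <- harmonic_power(time_frequency(cal), cal_sched, "O1", f, n)
  a_occ <- 10^((ref_db - d1) / 20)
  a_par <- 10^((target_ratio * ref_db - d1) / 20)
  amplitude_spec(f, c("occipital", "parietal"), n, c(a_occ, a_par))
}
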