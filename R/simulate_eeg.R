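#' Amplitude specification for simulated SSVEP responses
#'
#' Helper building the long-format amplitude table consumed by
#' [simulate_eeg()]. Each row assigns a sinusoid amplitude (microvolts) to
#' one harmonic of one stimulation frequency on one target (a lobe name or
#' a single 10-20 channel label).
#'
#' @param frequency Stimulation frequency (Hz) the row applies to.
#' @param target `"occipital"`, `"parietal"`, or a 10-20 channel label.
#' @param harmonic Harmonic number `n >= 1`; the sinusoid is at
#'   `frequency * harmonic` Hz.
#' @param amplitude Peak amplitude in microvolts.
#' @return A data frame with columns `frequency`, `target`, `harmonic`,
#'   `amplitude`; rows recycled to common length.
#' @examples
#' amplitude_spec(12, c("occipital", "parietal"), 1, c(10, 7))
#' @export
amplitude_spec <- function(frequency, target, harmonic, amplitude) {
  data.frame(frequency = as.numeric(frequency),
             target = as.character(target),
             harmonic = as.integer(harmonic),
             amplitude = as.numeric(amplitude),
             stringsAsFactors = FALSE)
}

resolve_target <- function(target) {
  if (target == "occipital") return(OCCIPITAL_ELECTRODES)
  if (target == "parietal") return(PARIETAL_ELECTRODES)
  if (target %in% MONTAGE_10_20) return(target)
  stop("amplitude target '", target, "' is neither a lobe nor a channel ",
       "in the 10-20 montage", call. = FALSE)
}

# 1/f ("pink") noise via spectral shaping of white Gaussian noise,
# normalized to unit standard deviation. Uses the current RNG stream.
pink_noise <- function(n) {
  if (n < 2L) return(rnorm(n))
  white <- rnorm(n)
  spec <- fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric two-sided frequency index
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Simulate an IPS-paradigm EEG recording with SSVEP responses
#'
#' Generates a 19-channel recording following a stimulation schedule.
#' During each stimulation block, targeted channels carry sinusoids at the
#' block frequency times the requested harmonics, superimposed on pink
#' (1/f) plus white noise; rest blocks carry noise only. Identical
#' arguments (including `seed`) give bitwise-identical recordings.
#'
#' @param schedule A `stim_schedule` from [make_ips_schedule()].
#' @param amplitudes Amplitude table from [amplitude_spec()]. May be
#'   `NULL` for a noise-only recording.
#' @param noise List with elements `pink` and `white`: standard deviations
#'   in microvolts of the 1/f and white noise components. Use
#'   `list(pink = 0, white = 0)` for a noise-free recording.
#' @param seed Integer seed; required.
#' @param sampling_rate Sampling rate in Hz (default 200).
#' @return An [eeg_recording()] with the schedule attached.
#' @examples
#' sched <- make_ips_schedule(12, 10, 0)
#' amps <- amplitude_spec(12, c("occipital", "parietal"), 1, c(10, 7))
#' rec <- simulate_eeg(sched, amps, noise = list(pink = 0, white = 0),
#'                     seed = 1)
#' @export
simulate_eeg <- function(schedule, amplitudes = NULL,
                         noise = list(pink = 1, white = 0.5), seed,
                         sampling_rate = 200) {
  stopifnot(inherits(schedule, "stim_schedule"))
  n_samp <- round(schedule$total_duration * sampling_rate)
  n_ch <- length(MONTAGE_10_20)
  nyquist <- sampling_rate / 2

  if (!is.null(amplitudes)) {
    stopifnot(is.data.frame(amplitudes))
    bad <- amplitudes$frequency * amplitudes$harmonic >= nyquist
    if (any(bad)) {
      stop("harmonic frequency at or above Nyquist (", nyquist, " Hz): ",
           paste(amplitudes$frequency[bad] * amplitudes$harmonic[bad],
                 collapse = ", "), call. = FALSE)
    }
    lapply(amplitudes$target, resolve_target)   # validates targets
  }

  with_seed(seed, {
    signal <- matrix(0, n_ch, n_samp, dimnames = list(MONTAGE_10_20, NULL))
    if (noise$pink > 0) {
      for (ch in seq_len(n_ch)) {
        signal[ch, ] <- signal[ch, ] + noise$pink * pink_noise(n_samp)
      }
    }
    if (noise$white > 0) {
      signal <- signal + matrix(rnorm(n_ch * n_samp, sd = noise$white),
                                n_ch, n_samp)
    }
    if (!is.null(amplitudes)) {
      t_all <- (seq_len(n_samp) - 1) / sampling_rate
      for (b in seq_len(nrow(schedule$blocks))) {
        blk <- schedule$blocks[b, ]
        idx <- sample_range(blk$onset, blk$offset, sampling_rate)
        rows <- which(amplitudes$frequency == blk$frequency)
        for (r in rows) {
          chans <- resolve_target(amplitudes$target[r])
          wave <- amplitudes$amplitude[r] *
            sin(2 * pi * blk$frequency * amplitudes$harmonic[r] * t_all[idx])
          signal[chans, idx] <- sweep(signal[chans, idx, drop = FALSE], 2,
                                      wave, `+`)
        }
      }
    }
    eeg_recording(signal, MONTAGE_10_20, sampling_rate, schedule)
  })
}
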