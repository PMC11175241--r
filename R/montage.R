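#' @keywords internal
#' @import stats
#' @importFrom utils write.csv read.csv
"_PACKAGE"

# 19-channel international 10-20 montage used throughout the package.
MONTAGE_10_20 <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "C3", "C4",
                   "T3", "T4", "T5", "T6", "P3", "P4", "O1", "O2",
                   "Fz", "Cz", "Pz")

PARIETAL_ELECTRODES <- c("P3", "P4", "C3", "C4", "Pz", "Cz")
OCCIPITAL_ELECTRODES <- c("O1", "O2")

# Canonical EEG bands, half-open [low, high) so each integer edge belongs
# to exactly one band (8 Hz -> alpha, 12 Hz -> beta).
EEG_BANDS <- list(
  "θ" = c(4, 8),
  "α" = c(8, 12),
  "β" = c(12, 30),
  "γ" = c(30, 50)
)

IPS_FREQUENCIES <- c(3, 5, 10, 12, 15, 20)

#' Electrode set for a cortical lobe
#'
#' Returns the named electrode set used for lobe-level averaging of power
#' and connectivity. The dorsal-stream analysis contrasts the parietal set
#' (P3, P4, C3, C4, Pz, Cz) against the occipital set (O1, O2).
#'
#' @param name `"parietal"` or `"occipital"`.
#' @return An object of class `lobe_set`: a list with `name` and
#'   `electrodes`.
#' @examples
#' lobe_set("occipital")$electrodes
#' @export
lobe_set <- function(name = c("parietal", "occipital")) {
  name <- match.arg(name)
  electrodes <- switch(name,
    parietal = PARIETAL_ELECTRODES,
    occipital = OCCIPITAL_ELECTRODES
  )
  structure(list(name = name, electrodes = electrodes), class = "lobe_set")
}

#' Canonical EEG frequency band
#'
#' Bands are half-open intervals `[low, high)` in Hz: theta 4-8, alpha
#' 8-12, beta 12-30, gamma 30-50. Accepts Greek letters or the spelled-out
#' English names.
#'
#' @param name Band name: one of `"theta"`, `"alpha"`, `"beta"`, `"gamma"`
#'   or the corresponding Greek letter.
#' @return An object of class `eeg_band`: list with `name` (Greek letter)
#'   and `range` (length-2 numeric, Hz).
#' @examples
#' eeg_band("alpha")$range
#' @export
eeg_band <- function(name) {
  ascii <- c(theta = "θ", alpha = "α", beta = "β",
             gamma = "γ")
  if (name %in% names(ascii)) name <- ascii[[name]]
  if (!name %in% names(EEG_BANDS)) {
    stop("unknown band: ", name, call. = FALSE)
  }
  structure(list(name = name, range = EEG_BANDS[[name]]), class = "eeg_band")
}

band_bins <- function(band, freqs) {
  freqs >= band$range[1] & freqs < band$range[2]
}

assert_montage <- function(labels) {
  if (!setequal(labels, MONTAGE_10_20) || length(labels) != 19L) {
    stop("channel labels must be the 19-channel 10-20 montage",
         call. = FALSE)
  }
  invisible(labels)
}
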