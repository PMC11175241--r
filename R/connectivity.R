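#' Construct a connectivity graph object
#'
#' @param weights Symmetric electrode x electrode matrix with zero
#'   diagonal, entries in `[0, 1]`.
#' @param f Stimulation frequency the graph belongs to (Hz).
#' @param band An [eeg_band()].
#' @return Object of class `connectivity_graph`.
#' @export
connectivity_graph <- function(weights, f = NA_real_, band = NULL) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (max(abs(weights - t(weights))) > 1e-10) {
    stop("weights must be symmetric", call. = FALSE)
  }
  if (any(diag(weights) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (min(weights) < -1e-12 || max(weights) > 1 + 1e-12) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  structure(list(weights = weights, f = f, band = band),
            class = "connectivity_graph")
}

# Hann-tapered segment FFTs for the stimulation block of frequency f:
# returns complex array (channels x frequency bins x segments) on the
# 1 Hz grid given by 1 s segments.
block_segment_ffts <- function(recording, f, seg_s = 1, overlap = 0.5) {
  fs <- recording$sampling_rate
  blk <- schedule_block(recording$schedule, f)
  idx <- sample_range(blk$onset, blk$offset, fs)
  W <- round(seg_s * fs)
  if (length(idx) < W) {
    stop("stimulation block shorter than one analysis segment",
         call. = FALSE)
  }
  hop <- max(1L, round(W * (1 - overlap)))
  starts <- seq(1L, length(idx) - W + 1L, by = hop)
  h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(W) - 1) / W)
  n_ch <- nrow(recording$signal)
  nbin <- W %/% 2L
  X <- array(0i, c(n_ch, nbin, length(starts)))
  for (ch in seq_len(n_ch)) {
    segs <- matrix(recording$signal[ch, idx[outer(seq_len(W) - 1L, starts,
                                                  `+`)]], W)
    Xc <- stats::mvfft(segs * h)
    X[ch, , ] <- Xc[2:(nbin + 1L), , drop = FALSE]   # drop DC
  }
  list(X = X, freqs = seq_len(nbin) * (fs / W),
       labels = recording$channel_labels)
}

wpli_from_ffts <- function(ffts, band) {
  sel <- which(band_bins(band, ffts$freqs))
  if (length(sel) == 0L) stop("band contains no frequency bins",
                              call. = FALSE)
  n_ch <- dim(ffts$X)[1]
  w <- matrix(0, n_ch, n_ch, dimnames = list(ffts$labels, ffts$labels))
  for (i in seq_len(n_ch - 1L)) {
    Xi <- ffts$X[i, sel, , drop = FALSE]
    for (j in (i + 1L):n_ch) {
      im <- Im(Xi * Conj(ffts$X[j, sel, , drop = FALSE]))
      den <- mean(abs(im))
      w[i, j] <- w[j, i] <- if (den > 0) abs(mean(im)) / den else 0
    }
  }
  w
}

#' Weighted phase lag index connectivity graph
#'
#' Computes the wPLI between every electrode pair over one stimulation
#' block, restricted to one frequency band. The estimator pools
#' Hann-tapered 1 s segments with 50\% overlap:
#' `|E[Im S_ij]| / E[|Im S_ij|]` over segments and in-band bins. wPLI is
#' bounded in `[0, 1]` and discounts zero-lag (volume-conducted) coupling.
#'
#' @param recording An [eeg_recording()] with schedule.
#' @param f Stimulation frequency whose block is analyzed.
#' @param band An [eeg_band()].
#' @param seg_s Segment length (s), default 1.
#' @param overlap Segment overlap fraction, default 0.5.
#' @return A [connectivity_graph()].
#' @export
wpli_graph <- function(recording, f, band, seg_s = 1, overlap = 0.5) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(band, "eeg_band"))
  if (band$range[2] > recording$sampling_rate / 2) {
    stop("band exceeds the Nyquist frequency", call. = FALSE)
  }
  ffts <- block_segment_ffts(recording, f, seg_s, overlap)
  connectivity_graph(wpli_from_ffts(ffts, band), f = f, band = band)
}

#' Onnela weighted clustering coefficient of one electrode
#'
#' Geometric-mean triangle intensity around node `e`:
#' `C(e) = sum_{i != j} (w_ei w_ej w_ij)^{1/3} / (deg(e) (deg(e) - 1))`
#' where `deg(e)` counts neighbors with nonzero weight. Defined as 0 when
#' `deg(e) < 2`. With an optional proportional threshold, only the top
#' `keep` fraction of off-diagonal weights (by magnitude) is retained
#' before the computation.
#'
#' @param graph A [connectivity_graph()].
#' @param e Electrode label or index.
#' @param keep Optional fraction in (0, 1] of strongest edges to keep.
#' @return Clustering coefficient in `[0, 1]` for weights in `[0, 1]`.
#' @export
clustering_coefficient <- function(graph, e, keep = NULL) {
  w <- graph$weights
  if (nrow(w) < 3L) stop("graph needs at least 3 nodes", call. = FALSE)
  if (!is.null(keep)) w <- proportional_threshold(w, keep)
  if (is.character(e)) e <- match(e, rownames(w))
  deg <- sum(w[e, ] > 0)
  if (deg < 2) return(0)
  v <- w[e, ]^(1 / 3)
  total <- drop(v %*% (w^(1 / 3)) %*% v)   # i = j and i,j = e terms vanish
  total / (deg * (deg - 1))
}

proportional_threshold <- function(w, keep) {
  stopifnot(keep > 0, keep <= 1)
  off <- w[upper.tri(w)]
  k <- ceiling(keep * length(off))
  cut <- sort(off, decreasing = TRUE)[k]
  w[w < cut] <- 0
  w
}

#' Lobe connectivity: electrode-averaged clustering coefficient
#'
#' @param graph A [connectivity_graph()] whose rows are 10-20 labels.
#' @param lobe A [lobe_set()].
#' @param keep Optional proportional threshold (see
#'   [clustering_coefficient()]).
#' @return Mean clustering coefficient over the lobe's electrodes.
#' @export
lobe_connectivity <- function(graph, lobe, keep = NULL) {
  missing <- setdiff(lobe$electrodes, rownames(graph$weights))
  if (length(missing) > 0) {
    stop("electrode(s) missing from graph: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mean(vapply(lobe$electrodes, clustering_coefficient, numeric(1),
              graph = graph, keep = keep))
}

lcr_from_graph <- function(graph, keep = NULL) {
  lc_o <- lobe_connectivity(graph, lobe_set("occipital"), keep)
  if (lc_o == 0) stop("occipital lobe connectivity is zero; ratio ",
                      "undefined", call. = FALSE)
  lobe_connectivity(graph, lobe_set("parietal"), keep) / lc_o
}

#' Lobe connectivity ratio (parietal / occipital)
#'
#' Dorsal-stream connectivity index: ratio of parietal to occipital lobe
#' connectivity for the wPLI graph of one (stimulation frequency, band)
#' pair.
#'
#' @inheritParams wpli_graph
#' @param keep Optional proportional threshold.
#' @return Dimensionless ratio.
#' @export
lobe_connectivity_ratio <- function(recording, f, band, keep = NULL, ...) {
  lcr_from_graph(wpli_graph(recording, f, band, ...), keep)
}

#' Band connectivity ratio within the parietal lobe
#'
#' Ratio of parietal lobe connectivity across two bands at one
#' stimulation frequency: the theta/beta ratio (TBR) or alpha/beta ratio
#' (ABR), named `<f>PS-P-TBR` / `<f>PS-P-ABR`.
#'
#' @inheritParams wpli_graph
#' @param b1 Numerator band: theta or alpha.
#' @param b2 Denominator band: beta.
#' @param keep Optional proportional threshold.
#' @return Dimensionless ratio.
#' @export
band_connectivity_ratio <- function(recording, f, b1, b2 = eeg_band("beta"),
                                    keep = NULL, ...) {
  if (!b1$name %in% c("θ", "α")) {
    stop("numerator band must be theta or alpha", call. = FALSE)
  }
  lc1 <- lobe_connectivity(wpli_graph(recording, f, b1, ...),
                           lobe_set("parietal"), keep)
  lc2 <- lobe_connectivity(wpli_graph(recording, f, b2, ...),
                           lobe_set("parietal"), keep)
  if (lc2 == 0) stop("denominator band connectivity is zero", call. = FALSE)
  lc1 / lc2
}

#' Extract all connectivity-ratio features from a recording
#'
#' For every stimulation frequency in the schedule and every canonical
#' band, computes the parietal/occipital lobe connectivity ratio
#' (`<f>PS-POR-<band>`, 24 features for the six-frequency session) and
#' the parietal theta/beta and alpha/beta band connectivity ratios
#' (`<f>PS-P-TBR`, `<f>PS-P-ABR`; 12 features). Segment FFTs are computed
#' once per block and shared across bands.
#'
#' @param recording An [eeg_recording()] with schedule.
#' @param keep Optional proportional threshold.
#' @param seg_s,overlap wPLI estimator parameters.
#' @return Named numeric vector of connectivity features.
#' @export
extract_connectivity_features <- function(recording, keep = NULL,
                                          seg_s = 1, overlap = 0.5) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.null(recording$schedule)) {
    stop("recording has no stimulation schedule", call. = FALSE)
  }
  bands <- lapply(names(EEG_BANDS), eeg_band)
  names(bands) <- names(EEG_BANDS)
  out <- numeric(0)
  for (f in recording$schedule$blocks$frequency) {
    ffts <- block_segment_ffts(recording, f, seg_s, overlap)
    lc <- list()
    for (bn in names(bands)) {
      g <- connectivity_graph(wpli_from_ffts(ffts, bands[[bn]]), f,
                              bands[[bn]])
      lc[[bn]] <- list(
        p = lobe_connectivity(g, lobe_set("parietal"), keep),
        o = lobe_connectivity(g, lobe_set("occipital"), keep)
      )
      out[sprintf("%gPS-POR-%s", f, bn)] <-
        if (lc[[bn]]$o > 0) lc[[bn]]$p / lc[[bn]]$o else NA_real_
    }
    beta_p <- lc[["β"]]$p
    out[sprintf("%gPS-P-TBR", f)] <-
      if (beta_p > 0) lc[["θ"]]$p / beta_p else NA_real_
    out[sprintf("%gPS-P-ABR", f)] <-
      if (beta_p > 0) lc[["α"]]$p / beta_p else NA_real_
  }
  out
}
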