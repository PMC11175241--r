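# Shared fixtures and independent oracles used across the suite.

# A noise-free recording with a single stimulation block.
noise_free_recording <- function(f = 10, amp = 3, target = "occipital",
                                 harmonic = 1, stim_dur = 10) {
  sched <- make_ips_schedule(f, stim_dur, 0)
  simulate_eeg(sched, amplitude_spec(f, target, harmonic, amp),
               noise = list(pink = 0, white = 0), seed = 1)
}

# Random symmetric [0,1] weight matrix with zero diagonal and 10-20 labels.
random_graph <- function(n = 19, labels = NULL, sparsity = 0) {
  w <- matrix(runif(n * n), n, n)
  w <- (w + t(w)) / 2
  if (sparsity > 0) w[w < sparsity] <- 0
  diag(w) <- 0
  if (is.null(labels) && n == 19) labels <- ssvepkiosk:::MONTAGE_10_20
  if (!is.null(labels)) dimnames(w) <- list(labels, labels)
  connectivity_graph(w)
}

# Exhaustive triple-enumeration oracle for the Onnela weighted clustering
# coefficient: direct double sum over ordered neighbor pairs.
onnela_oracle <- function(w, e) {
  n <- nrow(w)
  deg <- sum(w[e, ] > 0)
  if (deg < 2) return(0)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && i != e && j != e) {
        total <- total + (w[e, i] * w[e, j] * w[i, j])^(1 / 3)
      }
    }
  }
  total / (deg * (deg - 1))
}

# Brute-force Benjamini-Hochberg step-up: sort, scale by m/rank, enforce
# monotonicity from the largest rank down, cap at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Sample VR session parameters for round-trip tests.
session_params <- function(ttc = 60, errors = 2, scan = 30, fix = 55,
                           dist = 12) {
  list(time_to_completion = ttc, n_errors = errors, scanpath_length = scan,
       fixation_proportion = fix, hand_distance = dist)
}
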