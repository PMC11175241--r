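# Multilevel discrete wavelet transform with periodic extension.
# Daubechies-4 (8-tap) orthogonal filter pair; standard published
# coefficients (scaling filter sums to sqrt(2), unit energy).
DB4_LO <- c(0.23037781330885523, 0.71484657055254153,
            0.63088076792959036, -0.027983769416983849,
            -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278)
# quadrature mirror: hi[l] = (-1)^l * lo[L - 1 - l]
DB4_HI <- rev(DB4_LO) * c(1, -1, 1, -1, 1, -1, 1, -1) * -1

# Analysis: inner products with the periodized basis functions, i.e.
# correlation with the filter at even shifts: a[k] = sum_l h[l] x[2(k-1)+l]
dwt_step <- function(x, h) {
  n <- length(x)
  L <- length(h)
  idx <- outer(seq(1, n, by = 2), seq_len(L) - 1L, `+`)
  idx <- (idx - 1L) %% n + 1L
  as.numeric(matrix(x[idx], ncol = L) %*% h)
}

# Synthesis: upsample by two and circularly convolve with the same
# orthogonal filters, summing the low- and high-pass branches.
idwt_step <- function(a, d, lo = DB4_LO, hi = DB4_HI) {
  n <- 2L * length(a)
  up_a <- numeric(n); up_a[seq(1, n, by = 2)] <- a
  up_d <- numeric(n); up_d[seq(1, n, by = 2)] <- d
  L <- length(lo)
  out <- numeric(n)
  for (k in seq_len(L)) {
    sh <- (seq_len(n) - k) %% n + 1L
    out <- out + lo[k] * up_a[sh] + hi[k] * up_d[sh]
  }
  out
}

# x length must halve evenly at every level
dwt_periodic <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    details[[j]] <- dwt_step(a, DB4_HI)
    a <- dwt_step(a, DB4_LO)
  }
  list(approx = a, details = details)
}

idwt_periodic <- function(coeffs) {
  a <- coeffs$approx
  for (j in rev(seq_along(coeffs$details))) {
    a <- idwt_step(a, coeffs$details[[j]])
  }
  a
}
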