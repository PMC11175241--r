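phase_lag_recording <- function(lag_rad, f = 10, noise_sd = 0.05,
                                seed = 11) {
  fs <- 200
  n <- 2000
  t <- (0:(n - 1)) / fs
  set.seed(seed)
  sig <- matrix(rnorm(19 * n, sd = noise_sd), 19)
  rownames(sig) <- ssvepkiosk:::MONTAGE_10_20
  sig["O1", ] <- sig["O1", ] + sin(2 * pi * f * t)
  sig["O2", ] <- sig["O2", ] + sin(2 * pi * f * t - lag_rad)
  eeg_recording(sig, ssvepkiosk:::MONTAGE_10_20, fs,
                make_ips_schedule(f, n / fs, 0))
}

test_that("band definitions are half-open canonical intervals", {
  expect_equal(eeg_band("theta")$range, c(4, 8))
  expect_equal(eeg_band("alpha")$range, c(8, 12))
  expect_equal(eeg_band("beta")$range, c(12, 30))
  expect_equal(eeg_band("gamma")$range, c(30, 50))
  # 8 Hz belongs to alpha only, 12 Hz to beta only
  expect_true(ssvepkiosk:::band_bins(eeg_band("alpha"), 8))
  expect_false(ssvepkiosk:::band_bins(eeg_band("theta"), 8))
  expect_true(ssvepkiosk:::band_bins(eeg_band("beta"), 12))
  expect_false(ssvepkiosk:::band_bins(eeg_band("alpha"), 12))
  expect_error(eeg_band("delta"), "unknown band")
})

test_that("wPLI detects lagged coupling and discounts zero lag", {
  g90 <- wpli_graph(phase_lag_recording(pi / 2), 10, eeg_band("alpha"))
  expect_gt(g90$weights["O1", "O2"], 0.95)
  g0 <- wpli_graph(phase_lag_recording(0), 10, eeg_band("alpha"))
  expect_lt(g0$weights["O1", "O2"], 0.1)
  expect_equal(g90$weights, t(g90$weights))
  expect_true(all(diag(g90$weights) == 0))
  expect_true(all(g90$weights >= 0 & g90$weights <= 1))
})

test_that("wPLI is invariant to channel amplitude scaling", {
  rec <- phase_lag_recording(pi / 3)
  g1 <- wpli_graph(rec, 10, eeg_band("alpha"))
  rec$signal["O1", ] <- 7.3 * rec$signal["O1", ]
  rec$signal["P3", ] <- 0.1 * rec$signal["P3", ]
  g2 <- wpli_graph(rec, 10, eeg_band("alpha"))
  expect_equal(g1$weights, g2$weights, tolerance = 1e-10)
})

test_that("clustering coefficient matches the enumeration oracle", {
  # printed triangle example
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.8
  w[1, 3] <- w[3, 1] <- 0.6
  w[2, 3] <- w[3, 2] <- 0.4
  g <- connectivity_graph(w)
  expect_equal(clustering_coefficient(g, 1), (0.8 * 0.6 * 0.4)^(1 / 3),
               tolerance = 1e-10)

  # complete unit-weight triangle and open star
  w1 <- matrix(1, 3, 3); diag(w1) <- 0
  for (e in 1:3) {
    expect_equal(clustering_coefficient(connectivity_graph(w1), e), 1)
  }
  ws <- matrix(0, 5, 5); ws[1, 2:5] <- ws[2:5, 1] <- 0.7
  expect_equal(clustering_coefficient(connectivity_graph(ws), 1), 0)
  expect_equal(clustering_coefficient(connectivity_graph(ws), 2), 0)

  # random 19-node graphs, dense and sparsified
  set.seed(21)
  for (rep in 1:25) {
    g <- random_graph(19, sparsity = sample(c(0, 0.4, 0.8), 1))
    e <- sample(19, 1)
    expect_equal(clustering_coefficient(g, e),
                 onnela_oracle(g$weights, e), tolerance = 1e-10)
  }
})

test_that("lobe connectivity averages the lobe's electrodes", {
  set.seed(4)
  g <- random_graph(19)
  occ <- lobe_set("occipital")
  expect_equal(lobe_connectivity(g, occ),
               mean(c(clustering_coefficient(g, "O1"),
                      clustering_coefficient(g, "O2"))), tolerance = 1e-12)
  par <- lobe_set("parietal")
  oracle <- mean(vapply(par$electrodes, function(e) {
    onnela_oracle(g$weights, match(e, rownames(g$weights)))
  }, numeric(1)))
  expect_equal(lobe_connectivity(g, par), oracle, tolerance = 1e-10)
})

test_that("connectivity ratios are scale-invariant and arithmetic", {
  # ratios on planted lobe connectivity values via a synthetic wrapper
  set.seed(6)
  g <- random_graph(19)
  lcp <- lobe_connectivity(g, lobe_set("parietal"))
  lco <- lobe_connectivity(g, lobe_set("occipital"))
  expect_equal(ssvepkiosk:::lcr_from_graph(g), lcp / lco)

  # common scaling of all weights scales C by the factor, leaving the
  # ratio unchanged
  g2 <- connectivity_graph(g$weights * 0.5)
  expect_equal(ssvepkiosk:::lcr_from_graph(g2),
               ssvepkiosk:::lcr_from_graph(g), tolerance = 1e-10)
})

test_that("connectivity feature extraction emits the named 24 + 12 set", {
  sched <- make_ips_schedule(c(10, 15), 10, 0)
  rec <- simulate_eeg(sched, NULL, noise = list(pink = 1, white = 0.5),
                      seed = 31)
  feats <- extract_connectivity_features(rec)
  expect_equal(length(feats), 2 * 4 + 2 * 2)
  expect_true(all(c("10PS-POR-α", "15PS-P-TBR",
                    "10PS-P-ABR") %in% names(feats)))
  lcr_names <- grep("PS-POR-", names(feats), value = TRUE)
  expect_equal(length(lcr_names), 8)

  # single-frequency schedule gives 4 lobe connectivity ratios
  rec1 <- simulate_eeg(make_ips_schedule(10, 10, 0), NULL,
                       noise = list(pink = 1, white = 0.5), seed = 32)
  f1 <- extract_connectivity_features(rec1)
  expect_equal(sum(grepl("PS-POR-", names(f1))), 4)
  expect_true(all(c("10PS-P-TBR", "10PS-P-ABR") %in% names(f1)))
})

test_that("band connectivity ratio validates its numerator band", {
  rec <- simulate_eeg(make_ips_schedule(10, 10, 0), NULL,
                      noise = list(pink = 1, white = 0.5), seed = 33)
  tbr <- band_connectivity_ratio(rec, 10, eeg_band("theta"))
  abr <- band_connectivity_ratio(rec, 10, eeg_band("alpha"))
  expect_true(is.finite(tbr) && tbr > 0)
  expect_true(is.finite(abr) && abr > 0)
  expect_error(band_connectivity_ratio(rec, 10, eeg_band("gamma")),
               "theta or alpha")
})
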