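test_that("IPS schedule lays out alternating stimulation and rest blocks", {
  s <- make_ips_schedule(c(3, 5, 10, 12, 15, 20), 10, 10)
  expect_equal(s$total_duration, 120)
  expect_equal(nrow(s$blocks), 6)
  expect_equal(s$blocks$frequency, c(3, 5, 10, 12, 15, 20))
  # non-overlapping and ordered, each block exactly the configured length
  expect_true(all(diff(s$blocks$onset) > 0))
  expect_equal(s$blocks$offset - s$blocks$onset, rep(10, 6))
  expect_true(all(s$rest_blocks$onset >= s$blocks$offset))

  s1 <- make_ips_schedule(10, 10, 0)
  expect_equal(s1$total_duration, 10)
  expect_equal(nrow(s1$blocks), 1)
  expect_equal(nrow(s1$rest_blocks), 0)

  expect_equal(make_ips_schedule(c(3, 5), 5, 5)$total_duration, 20)

  expect_error(make_ips_schedule(numeric(0), 10, 10), "non-empty")
  expect_error(make_ips_schedule(10, -1, 10), ">= 0")
})

test_that("EEG simulator is deterministic and spectrally correct", {
  sched <- make_ips_schedule(c(10, 15), 5, 5)
  amps <- amplitude_spec(c(10, 15), "occipital", 1, c(5, 5))

  a <- simulate_eeg(sched, amps, seed = 99)
  b <- simulate_eeg(sched, amps, seed = 99)
  expect_identical(a$signal, b$signal)

  z <- simulate_eeg(sched, NULL, noise = list(pink = 0, white = 0),
                    seed = 1)
  expect_true(all(z$signal == 0))

  # noise-free block has its time-frequency argmax at f on every
  # stimulated channel
  rec <- simulate_eeg(make_ips_schedule(12, 10, 0),
                      amplitude_spec(12, "occipital", 1, 8),
                      noise = list(pink = 0, white = 0), seed = 2)
  tf <- time_frequency(rec)
  interior <- tf$times > 0.5 & tf$times < 9.5
  for (ch in c("O1", "O2")) {
    peaks <- apply(tf$power[ch, , interior], 2, which.max)
    expect_true(all(tf$frequencies[peaks] == 12))
  }

  expect_error(
    simulate_eeg(sched, amplitude_spec(10, "occipital", 12, 1), seed = 1),
    "Nyquist")
  expect_error(
    simulate_eeg(sched, amplitude_spec(10, "XX9", 1, 1), seed = 1),
    "montage")
})

test_that("recording invariants are enforced", {
  sched <- make_ips_schedule(10, 10, 0)
  expect_error(
    eeg_recording(matrix(0, 5, 2000), paste0("ch", 1:5), 200, sched),
    "montage")
  expect_error(
    eeg_recording(matrix(0, 19, 1999), ssvepkiosk:::MONTAGE_10_20, 200,
                  sched),
    "sample count")
})

test_that("VR session generator hits its requested feature targets", {
  log <- simulate_vr_session(session_params(ttc = 60, errors = 0), seed = 3)
  feats <- extract_behavioral_features(log)
  expect_equal(feats$time_to_completion, 60, tolerance = 0.1 / 60)
  expect_equal(feats$n_errors, 0)
  expect_false(any(log$events$is_error))

  # requested hand speed through distance: 0.20 m/s over 60 s = 12 m
  log2 <- simulate_vr_session(
    list(time_to_completion = 60, n_errors = 1, scanpath_length = 25,
         fixation_proportion = 40, hand_speed = 0.20), seed = 4)
  f2 <- extract_behavioral_features(log2)
  expect_equal(f2$hand_speed, 0.20, tolerance = 0.02)
  expect_equal(f2$hand_distance, 12, tolerance = 0.02)

  expect_error(simulate_vr_session(session_params(ttc = -5), seed = 1),
               "positive")
  expect_identical(simulate_vr_session(session_params(), seed = 5),
                   simulate_vr_session(session_params(), seed = 5))
})

test_that("cohort copula recovers independence and planted correlation", {
  # independent features: within-group cross-modal correlations near zero
  spec0 <- cohort_spec(n_per_group = 4000, cross_modal = NULL, seed = 8)
  tab0 <- simulate_cohort(spec0)
  hc <- tab0[tab0$group == "hc", ]
  r0 <- cor(hc$hand_speed, hc[["12PS-POR-1H"]])
  expect_lt(abs(r0), 0.05)

  # planted -0.40 between 12PS-POR-1H and hand speed
  tab <- simulate_cohort(cohort_spec(n_per_group = 4000, seed = 9))
  hc <- tab[tab$group == "hc", ]
  expect_equal(cor(hc[["12PS-POR-1H"]], hc$hand_speed), -0.40,
               tolerance = 0.03 / 0.40)

  # marginal recovery within 3 standard errors
  m <- mean(hc$time_to_completion)
  se <- 54.94 / sqrt(4000)
  expect_lt(abs(m - 50.00), 3 * se)

  expect_identical(simulate_cohort(cohort_spec(n_per_group = 5, seed = 2)),
                   simulate_cohort(cohort_spec(n_per_group = 5, seed = 2)))

  # non-PSD correlation completion is rejected
  bad <- cross_modal_targets()
  bad$r <- c(0.99, 0.99, -0.99, -0.99, 0.99, 0.99)
  expect_error(simulate_cohort(cohort_spec(cross_modal = bad, seed = 1)),
               "positive semi-definite")
})

test_that("cohort tables have the expected layout", {
  tab <- simulate_cohort(cohort_spec(n_per_group = 12, seed = 5))
  expect_equal(nrow(tab), 24)
  expect_equal(levels(tab$group), c("hc", "amci"))
  expect_true(all(c("scanpath_length", "time_to_completion",
                    "12PS-POR-1H", "3PS-POR-α",
                    "15PS-P-TBR") %in% names(tab)))
  expect_true(all(tab$n_errors >= 0 & tab$n_errors == round(tab$n_errors)))
  expect_true(all(tab$fixation_proportion >= 0 &
                    tab$fixation_proportion <= 100))
})
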