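test_that("SEM events are exact opposite-phase tapered sinusoids", {
  ev <- generateSemEvent(0.4, 100, 3, 0, fs = 500)
  expect_equal(ev$hl, -ev$hr)
  expect_equal(max(abs(ev$hl)), 100, tolerance = 1e-4)
  # difference trace doubles the excursion
  expect_equal(max(abs(ev$hl - ev$hr)), 200, tolerance = 1e-4)
})

test_that("SEM sinusoid phase matches the closed form", {
  # 0.4 Hz over 3 s completes 1.2 cycles; un-windowed zero crossings at
  # multiples of 1.25 s
  fs <- 500
  ev <- generateSemEvent(0.4, 100, 3, 0, fs = fs)
  t <- (seq_along(ev$hl) - 1) / fs
  mid <- which(t > 0.4 & t < 2.6)           # away from the 10% taper
  expect_equal(ev$hl[mid], 100 * sin(2 * pi * 0.4 * t[mid]),
               tolerance = 1e-9)
  i125 <- which.min(abs(t - 1.25))
  expect_lt(abs(ev$hl[i125]), 100 * 2 * pi * 0.4 / fs + 1e-9)
  expect_equal(floor(0.4 * 3 / 0.5), 2)     # 1.2 cycles -> 2 interior crossings
})

test_that("SEM event parameters outside the criteria are rejected", {
  expect_error(generateSemEvent(1.0, 100, 3, 0), "frequency")
  expect_error(generateSemEvent(0.4, 10, 3, 0), "amplitude")
  expect_error(generateSemEvent(0.4, 100, 1.5, 0), "duration")
  expect_error(generateSemEvent(0.4, 100, 3, 400), "onset")
})

test_that("saccades are opposite-phase steps with the stated rise time", {
  fs <- 500
  sc <- generateSaccade(150, rise_ms = 20, fs = fs, plateau_s = 0.5)
  expect_equal(sc$hl, -sc$hr)
  expect_equal(max(sc$hl), 150)
  expect_equal(sc$hl[length(sc$hl)], 150)   # sustained plateau
  # 10-90% rise of a linear ramp is 80% of the nominal rise time
  i10 <- which(sc$hl >= 0.1 * 150)[1]
  i90 <- which(sc$hl >= 0.9 * 150)[1]
  expect_equal((i90 - i10) / fs * 1000, 16, tolerance = 4)
  expect_error(generateSaccade(-5), "non-negative")
  z <- generateSaccade(0)
  expect_true(all(z$hl == 0) && all(z$hr == 0))
})

test_that("recordings are seed-deterministic", {
  cfg <- smallSimConfig(seed = 7)
  r1 <- simulateRecording(cfg)
  r2 <- simulateRecording(cfg)
  expect_identical(r1@signals, r2@signals)
  expect_identical(intervals(r1), intervals(r2))
  r3 <- simulateRecording(smallSimConfig(seed = 8))
  expect_false(identical(r1@signals, r3@signals))
})

test_that("common-mode construction cancels exactly", {
  # no eye movement, drift or noise: Hl == Hr, and Hl + Hr is twice the
  # EEG component
  cfg <- simConfig(duration_s = 20, n_sem_events = 0, n_saccades = 0,
                   noise_sd_uv = 0, drift_amp_uv = 0, alpha_amp_uv = 10,
                   seed = 3)
  rec <- simulateRecording(cfg)
  expect_equal(max(abs(channel(rec, "Hl") - channel(rec, "Hr"))), 0)
  der <- deriveChannels(channel(rec, "Hl"), channel(rec, "Hr"))
  expect_true(all(der$HEOG == 0))
  expect_equal(der$HSUM, 2 * channel(rec, "Hl"))
  # conversely, pure eye movement has zero common mode
  cfg2 <- simConfig(duration_s = 60, n_sem_events = 3, n_saccades = 0,
                    noise_sd_uv = 0, drift_amp_uv = 0, alpha_amp_uv = 0,
                    eeg_bg_sd_uv = 0, seed = 3)
  rec2 <- simulateRecording(cfg2)
  der2 <- deriveChannels(channel(rec2, "Hl"), channel(rec2, "Hr"))
  # HSUM retains only the onset-difference residual of each event, which is
  # tiny relative to the eye signal it cancels
  expect_lt(max(abs(der2$HSUM)), 1e-9 + max(abs(der2$HEOG)) * 0.2)
})

test_that("ground-truth intervals are sorted, disjoint and cover the recording", {
  rec <- simulateRecording(smallSimConfig(seed = 11))
  iv <- intervals(rec)
  expect_true(all(diff(iv$start_s) > 0))
  expect_true(all(iv$end_s[-nrow(iv)] <= iv$start_s[-1] + 1e-9))
  expect_equal(iv$start_s[1], 0)
  expect_equal(iv$end_s[nrow(iv)], 60)
  expect_true(all(iv$label %in% c("SEM", "NONSEM")))
  expect_equal(sum(iv$label == "SEM"), 3)
})

test_that("infeasible event placement reports requested vs feasible", {
  cfg <- simConfig(duration_s = 30, n_sem_events = 8,
                   sem_duration_range = c(3, 4), seed = 1)
  expect_error(simulateRecording(cfg), "non-overlapping")
})

test_that("generated SEM events satisfy the labeling criteria; saccades do not", {
  rec <- simulateRecording(simConfig(duration_s = 120, n_sem_events = 5,
                                     n_saccades = 8, seed = 5))
  fs <- samplingRate(rec)
  iv <- intervals(rec)
  sem <- iv[iv$label == "SEM", ]
  for (i in seq_len(nrow(sem))) {
    idx <- round(sem$start_s[i] * fs) +
      seq_len(round((sem$end_s[i] - sem$start_s[i]) * fs))
    cr <- checkSemCriteria(channel(rec, "Hl")[idx], channel(rec, "Hr")[idx], fs)
    expect_true(cr$passed)
  }
})
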