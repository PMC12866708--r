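test_that("ratio computation is exact elementwise and guards the denominator", {
  t <- seq(0, 1, by = 0.02)
  rt <- ratiometric_trace(t, f340 = rep(500, length(t)),
                          f380 = rep(500, length(t)))
  expect_equal(unique(compute_ratio(rt)$f), 1)
  rt2 <- ratiometric_trace(t, f340 = 0.55 * rep(800, length(t)),
                           f380 = rep(800, length(t)))
  expect_equal(unique(round(compute_ratio(rt2)$f, 12)), 0.55)
  rt3 <- generate_calcium_trace(transient_truth(
    mode = "ratiometric", rhythm = "paced", beat_rate_hz = 0.5,
    amplitude = 0.6, diastolic_level = 0.5, noise_sd = 0, seed = 1))
  expect_equal(max(compute_ratio(rt3)$f), 1.1, tolerance = 1e-2)
  bad <- ratiometric_trace(t, f340 = rep(1, length(t)),
                           f380 = rep(c(100, -1), length.out = length(t)))
  expect_error(compute_ratio(bad), "F380")
})

test_that("paced detection finds exactly one beat per pacing cycle", {
  tr <- generate_calcium_trace(transient_truth(rhythm = "paced",
                                               beat_rate_hz = 0.5,
                                               duration_s = 20, seed = 1))
  beats <- detect_transients(tr, rhythm = "paced", pacing_hz = 0.5)
  expect_equal(nrow(beats), 10)
  # onset close to the true grid onset (10 %-crossing definition plus the
  # residual decay tail shift the detected onset by a few samples at most)
  expect_lt(max(abs(beats$onset_time_s - seq(0, 18, by = 2))), 0.1)
})

test_that("flat traces yield zero beats", {
  flat <- fluorescence_trace(seq(0, 10, by = 0.02), rep(3, 501))
  expect_equal(nrow(detect_transients(flat)), 0)
  feats <- extract_features(flat)
  expect_true(is.na(feats$decay_tau_s))
  expect_match(feats$reason, "fewer than 2 beats")
})

test_that("noisy detection matches the noiseless-twin threshold oracle", {
  for (seed in c(11, 12, 13)) {
    tt_noisy <- transient_truth(rhythm = "spontaneous", beat_rate_hz = 1,
                                decay_tau_s = 0.25, rise_time_s = 0.08,
                                duration_s = 30, noise_sd = 0.1, seed = seed)
    tt_clean <- transient_truth(rhythm = "spontaneous", beat_rate_hz = 1,
                                decay_tau_s = 0.25, rise_time_s = 0.08,
                                duration_s = 30, noise_sd = 0, seed = seed)
    noisy <- generate_calcium_trace(tt_noisy)
    clean <- generate_calcium_trace(tt_clean)
    oracle_n <- threshold_beat_count(clean$f, diastolic = 1, amplitude = 1)
    beats <- detect_transients(noisy)
    expect_equal(nrow(beats), oracle_n)
  }
})

test_that("features are exact on noiseless traces", {
  tr <- generate_calcium_trace(transient_truth(
    rhythm = "spontaneous", beat_rate_hz = 0.4, amplitude = 1,
    rise_time_s = 0.1, decay_tau_s = 0.5, duration_s = 20, noise_sd = 0,
    seed = 3))
  f <- extract_features(tr)
  expect_equal(f$decay_tau_s, 0.5, tolerance = 1e-3)
  # onset at the 10 % crossing: measured rise is 0.9 of the ramp +/- 1 sample
  expect_equal(f$rise_time_s, 0.1, tolerance = 0.2)
  expect_lt(abs(f$rise_time_s - 0.1), 0.02)
  expect_equal(f$diastolic_level, 1, tolerance = 0.01)
  expect_gt(f$fit_r2, 0.999)
})

test_that("decay tau is recovered within 5 percent at 20 dB SNR", {
  errs <- vapply(0:49, function(s) {
    tr <- generate_calcium_trace(transient_truth(
      rhythm = "spontaneous", beat_rate_hz = 0.4, amplitude = 1,
      rise_time_s = 0.12, decay_tau_s = 0.4, noise_sd = 0.1,
      duration_s = 20, seed = s))
    abs(extract_features(tr)$decay_tau_s - 0.4) / 0.4
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("tau estimator bias vanishes as noise goes to zero", {
  bias <- vapply(c(0.1, 0.03, 0.01, 0), function(ns) {
    taus <- vapply(1:10, function(s) {
      tr <- generate_calcium_trace(transient_truth(
        rhythm = "spontaneous", beat_rate_hz = 0.4, decay_tau_s = 0.4,
        noise_sd = ns, duration_s = 20, seed = s))
      extract_features(tr)$decay_tau_s
    }, numeric(1))
    abs(mean(taus) - 0.4)
  }, numeric(1))
  expect_true(all(diff(bias) <= 2e-3))  # decreasing up to seed noise
  expect_lt(bias[4], 1e-3)
  expect_gt(bias[1], bias[4])
})

test_that("single-channel features are invariant to intensity scaling", {
  tr <- generate_calcium_trace(transient_truth(
    rhythm = "spontaneous", beat_rate_hz = 0.4, noise_sd = 0.05,
    duration_s = 20, seed = 8))
  f1 <- extract_features(tr)
  tr2 <- fluorescence_trace(tr$time_s, tr$f * 37.5)
  f2 <- extract_features(tr2)
  for (col in c("amplitude", "rise_time_s", "decay_tau_s", "beat_rate_bpm",
                "diastolic_level"))
    expect_equal(f1[[col]], f2[[col]], tolerance = 1e-6)
})

test_that("ratiometric diastolic level is recovered within 2 percent at 20 dB", {
  ests <- vapply(1:20, function(s) {
    rt <- generate_calcium_trace(transient_truth(
      mode = "ratiometric", rhythm = "paced", beat_rate_hz = 0.5,
      amplitude = 0.6, diastolic_level = 0.5, decay_tau_s = 0.3,
      noise_sd = 0.06, duration_s = 20, seed = s))
    analyze_calcium_trace(rt, rhythm = "paced", pacing_hz = 0.5)$diastolic_level
  }, numeric(1))
  expect_lt(median(abs(ests - 0.5) / 0.5), 0.02)
})

test_that("beat rate comes from the peak-to-peak span", {
  tr <- generate_calcium_trace(transient_truth(
    rhythm = "paced", beat_rate_hz = 0.5, duration_s = 20, noise_sd = 0,
    seed = 1))
  f <- extract_features(tr, rhythm = "paced", pacing_hz = 0.5)
  expect_equal(f$beat_rate_bpm, 30, tolerance = 1e-6)
  expect_equal(f$n_beats, 10L)
})
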