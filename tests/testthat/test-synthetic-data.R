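test_that("EEG generator honours duration, rate and determinism", {
  p <- focus_profile(c(0, 10), c(0.3, 0.7))
  rec <- generate_eeg(10, p, seed = 3)
  expect_equal(nrow(rec$data), 256 * 10)
  expect_equal(ncol(rec$data), 4)
  expect_equal(nrow(rec$gyro), nrow(rec$data))

  rec2 <- generate_eeg(10, p, seed = 3)
  expect_identical(rec$data, rec2$data)
  expect_identical(rec$gyro, rec2$gyro)

  rec3 <- generate_eeg(10, p, seed = 4)
  expect_false(identical(rec$data, rec3$data))
})

test_that("focus profiles reject invalid values", {
  expect_error(focus_profile(c(0, 1), c(0.5, NaN)), "finite")
  expect_error(focus_profile(c(0, 1), c(-0.1, 0.5)), "\\[0, 1\\]")
  expect_error(focus_profile(c(1, 0), c(0.5, 0.5)), "increasing")
  expect_error(generate_eeg(-5, focus_profile(0, 0.5)))
})

test_that("planted alpha coupling is recoverable from band powers", {
  # noise-free generator, alpha only, coupling 1: alpha power must track
  # (1 - focus)^2, i.e. correlate strongly negatively with the profile
  set.seed(5)
  p <- focus_profile(seq(0, 60, by = 1), runif(61, 0.1, 0.9))
  rec <- generate_eeg(60, p, seed = 2, blink_rate = 0, motion_rate = 0,
                      background_sd = 0, sensor_sd = 0, beta_amp = 0,
                      theta_amp = 0, delta_amp = 0, coupling = 1)
  segs <- segment_recording(rec)
  fm <- feature_matrix(rec, segs)
  prof <- vapply(segs$start_s, function(t0) {
    i0 <- round(t0 * 256) + 1
    mean(rec$truth$profile[i0:(i0 + 1279)])
  }, numeric(1))
  expect_lte(cor(fm[, "pow_AF7_alpha"], prof), -0.9)
  expect_lte(cor(fm[, "pow_TP10_alpha"], prof), -0.9)
  # and the beta side of the coupling is increasing
  rec2 <- generate_eeg(60, p, seed = 2, blink_rate = 0, motion_rate = 0,
                       background_sd = 0, sensor_sd = 0, alpha_amp = 0,
                       theta_amp = 0, delta_amp = 0, coupling = 1)
  fm2 <- feature_matrix(rec2, segs)
  expect_gte(cor(fm2[, "pow_AF7_beta"], prof), 0.9)
})

test_that("cohorts are balanced with one condition per session", {
  coh <- tiny_cohort()
  expect_equal(length(coh$sessions), 16)
  per_part <- table(coh$schedule$participant, coh$schedule$condition)
  expect_true(all(per_part == 1))
  # counterbalancing: each condition appears once in every session position
  per_pos <- table(coh$schedule$session, coh$schedule$condition)
  expect_true(all(per_pos == 1))
  # six self-report labels per session
  expect_equal(nrow(coh$reports), 16 * 6)
  expect_true(all(coh$reports$focus >= 0 & coh$reports$focus <= 1))
})

test_that("zero effect and zero noise give identical latent statistics", {
  coh <- generate_cohort(
    4, effect = c(silence = 0, playlistA = 0, playlistB = 0, soundscape = 0),
    noise = 0, seed = 11, profile_sd = 0, session_jitter_sd = 0,
    durations = list(preferred = 20, arithmetic = 10, creativity = 10,
                     game = 8))
  cs <- neurofocus:::latent_condition_summary(coh)
  spread <- tapply(cs$focus, cs$participant, function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
})

test_that("out-of-range planted offsets are clipped with a warning record", {
  coh <- generate_cohort(
    3, effect = c(silence = 0, playlistA = 0, playlistB = 0, soundscape = 0.9),
    noise = 0, seed = 2,
    durations = list(preferred = 20, arithmetic = 10, creativity = 10,
                     game = 8))
  expect_false(is.null(coh$clip_log))
  expect_true(all(coh$clip_log$n_clipped > 0))
  for (ses in coh$sessions) {
    expect_true(all(ses$profile$values >= 0 & ses$profile$values <= 1))
  }
})

test_that("audio generator produces silence, white noise and determinism", {
  sil <- generate_audio(1, list(level = 0))
  expect_true(all(sil$samples == 0))

  wn <- generate_audio(2, list(brightness = 0.5, tempo_bpm = 0,
                               tone_level = 0), seed = 8)
  st <- short_time_audio_features(wn)
  # flat spectrum: sub-band entropy within 5% of its maximum log2(10)
  expect_gt(mean(st[, "spectral_entropy"]), 0.95 * log2(10))

  wn2 <- generate_audio(2, list(brightness = 0.5, tempo_bpm = 0,
                                tone_level = 0), seed = 8)
  expect_identical(wn$samples, wn2$samples)
  expect_true(all(abs(wn$samples) <= 1))
})

test_that("song sets plant a monotone brightness-to-focus map", {
  songs <- make_song_set(6, duration_s = 31, seed = 4)
  b <- vapply(songs, function(s) s$focus_target, numeric(1))
  cent <- vapply(songs, function(s) {
    mean(short_time_audio_features(s)[, "spectral_centroid"])
  }, numeric(1))
  expect_gt(cor(b, cent, method = "spearman"), 0.9)
})
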