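make_rec <- function(x, fs = 256, ...) {
  eeg_recording(cbind(x, x, x, x), fs = fs, ...)
}

test_that("band-pass and notch have the specified frequency response", {
  fs <- 256
  t <- (0:(fs * 20 - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))

  r60 <- filter_recording(make_rec(sin(2 * pi * 60 * t)))
  expect_lt(20 * log10(rms(r60$data[, 1]) / rms(sin(2 * pi * 60 * t))), -20)

  r10 <- filter_recording(make_rec(sin(2 * pi * 10 * t)))
  expect_lt(abs(20 * log10(rms(r10$data[, 1]) / rms(sin(2 * pi * 10 * t)))), 1)

  rdc <- filter_recording(make_rec(rep(100, length(t))))
  expect_lt(abs(mean(rdc$data[, 1])), 1)

  expect_error(filter_recording(make_rec(sin(t), fs = 100)), "too low")
})

test_that("filtering is idempotent up to tolerance and preserves length", {
  rec <- tiny_rec(seed = 2, duration = 20)
  f1 <- filter_recording(rec)
  f2 <- filter_recording(f1)
  expect_equal(nrow(f1$data), nrow(rec$data))
  rms1 <- sqrt(mean(f1$data[, 1]^2))
  rms2 <- sqrt(mean(f2$data[, 1]^2))
  expect_lt(abs(rms2 - rms1) / rms1, 0.01)
})

test_that("segment counts follow the sliding-window formula", {
  for (dur in c(12, 30, 61.25)) {
    rec <- tiny_rec(seed = 1, duration = dur, blink_rate = 0, motion_rate = 0)
    expect_equal(nrow(segment_recording(rec)),
                 floor((dur - 5) / 0.2 + 1e-9) + 1)
  }
  # overlap fraction of consecutive windows is 96%
  expect_equal((5 - 0.2) / 5, 0.96)
  # shorter than one window: empty, not an error
  short <- tiny_rec(seed = 1, duration = 4)
  expect_equal(nrow(segment_recording(short)), 0)
})

test_that("headband QC flags misplaced channels by raw SD", {
  set.seed(3)
  good <- rnorm(1000, 0, 20)
  bad <- rnorm(1000, 0, 600)
  rec <- eeg_recording(cbind(good, bad, good, good))
  qc <- qc_headband(rec)
  expect_equal(unname(qc), c("pass", "misplaced", "pass", "pass"))
  # boundary: SD exactly 500 passes (strict inequality)
  exact <- rep(c(-500, 0, 500), 100)
  expect_equal(sd(exact[1:3]), 500)
  expect_equal(unname(qc_headband(make_rec(exact[1:3]))),
               rep("pass", 4))
  expect_error(qc_headband(eeg_recording(matrix(0, 1, 4))), "SD")
})

test_that("motion gating excludes calibration but not Preferred Task", {
  fs <- 256
  n <- fs * 20
  iv <- data.frame(task = c("preferred", "arithmetic"),
                   start_s = c(0, 10), end_s = c(10, 20))
  gyro <- matrix(rnorm(n * 3, 0, 0.5), n, 3)
  burst <- seq(fs * 6 + 1, fs * 9) # inside preferred
  burst2 <- seq(fs * 15 + 1, fs * 18) # inside arithmetic
  gyro[c(burst, burst2), ] <- gyro[c(burst, burst2), ] + 50
  rec <- eeg_recording(matrix(rnorm(n * 4, 0, 10), n, 4), gyro = gyro,
                       intervals = iv)
  segs <- segment_recording(rec)
  moving_pref <- segs$task == "preferred" & segs$motion != "static"
  moving_cal <- segs$task == "arithmetic" & segs$motion != "static"
  expect_true(any(moving_pref) && any(moving_cal))
  expect_true(all(segs$retained[moving_pref]))
  expect_false(any(segs$retained[moving_cal]))
  # zero gyro: static and retained everywhere
  rec0 <- eeg_recording(rec$data, gyro = matrix(0, n, 3), intervals = iv)
  segs0 <- segment_recording(rec0)
  expect_true(all(segs0$motion == "static"))
  expect_true(all(segs0$retained))
})

test_that("missing gyroscope data degrades to static with a warning", {
  rec <- eeg_recording(matrix(rnorm(256 * 6 * 4), ncol = 4))
  expect_warning(segs <- segment_recording(rec), "gyroscope")
  expect_true(all(segs$motion == "static"))
})

test_that("blink detection recovers planted blink rates", {
  flat <- eeg_recording(matrix(0, 256 * 10, 4))
  expect_equal(blink_rate(flat), 0)

  p <- focus_profile(c(0, 60), c(0.5, 0.5))
  rec <- generate_eeg(60, p, seed = 9, blink_rate = 16, motion_rate = 0)
  planted <- length(rec$truth$blink_times)
  est <- blink_rate(rec)
  expect_lt(abs(est - planted) / planted, 0.2)

  # cohort-level mean near the norm of 16/min
  rates <- vapply(1:10, function(i) {
    blink_rate(generate_eeg(60, p, seed = 100 + i, blink_rate = 16,
                            motion_rate = 0))
  }, numeric(1))
  expect_gte(mean(rates), 13)
  expect_lte(mean(rates), 19)
})
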