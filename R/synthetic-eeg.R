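#' Latent focus profile
#'
#' A latent focus trajectory in `[0, 1]` over time. The profile stands in for
#' the unobservable ground truth that self-reports and decoded traces estimate:
#' synthetic EEG is coupled to it, and recovery experiments score decoders
#' against it.
#'
#' @param times numeric vector of seconds, strictly increasing.
#' @param values focus values in `[0, 1]`, same length as `times`.
#' @return an object of class `focus_profile` with fields `times`, `values`.
#' @examples
#' p <- focus_profile(0:9, seq(0.2, 0.8, length.out = 10))
#' @export
focus_profile <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 1)
  if (any(!is.finite(values)) || any(!is.finite(times))) {
    stop("focus profile must be finite")
  }
  if (any(diff(times) <= 0)) stop("profile times must be strictly increasing")
  if (any(values < 0 | values > 1)) stop("focus values must lie in [0, 1]")
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "focus_profile")
}

# Sample a profile on an arbitrary time grid (constant extrapolation).
profile_at <- function(profile, t) {
  if (length(profile$times) == 1L) {
    return(rep(profile$values, length(t)))
  }
  stats::approx(profile$times, profile$values, xout = t, rule = 2)$y
}

#' Smooth random focus profile
#'
#' Ornstein-Uhlenbeck fluctuation around a baseline, squashed into `[0, 1]`.
#' Used by [generate_cohort()] to create per-session latent dynamics with a
#' controllable timescale.
#'
#' @param duration_s length in seconds; the profile is sampled at 1 Hz.
#' @param baseline central focus level.
#' @param sd stationary standard deviation of the fluctuation.
#' @param tau_s fluctuation timescale in seconds.
#' @param seed integer seed.
#' @return a [focus_profile()] plus an attribute `n_clipped` counting samples
#'   clipped into `[0, 1]`.
#' @export
random_profile <- function(duration_s, baseline = 0.5, sd = 0.1, tau_s = 60,
                           seed = NULL) {
  n <- max(2L, ceiling(duration_s)) + 1L
  with_seed(seed, {
    phi <- exp(-1 / tau_s)
    eps <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sd)
    for (i in 2:n) x[i] <- phi * x[i - 1] + eps[i]
    raw <- baseline + x
    clipped <- sum(raw < 0 | raw > 1)
    p <- focus_profile(seq(0, duration_s, length.out = n), clip01(raw))
    attr(p, "n_clipped") <- clipped
    p
  })
}

# 1/f ("pink") noise of unit variance via spectral shaping of white noise.
pink_noise <- function(n) {
  if (n < 4) return(stats::rnorm(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  k <- pmin(k, n - k) # symmetric frequency index
  g <- ifelse(k == 0, 0, 1 / sqrt(k))
  y <- Re(stats::fft(X * g, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' EEG recording container
#'
#' Four-channel scalp EEG in microvolts sampled at `fs` Hz (frontal AF7/AF8
#' and temporal TP9/TP10, as on a consumer headband), an aligned 3-axis
#' gyroscope series in deg/s, named task intervals (half-open `[start, end)`
#' in seconds from recording start) and an audio condition label.
#'
#' @param data numeric matrix, samples x 4, columns `AF7, AF8, TP9, TP10` (uV).
#' @param fs sampling rate in Hz.
#' @param gyro numeric matrix, samples x 3 (`gyro_x/y/z`, deg/s), same length
#'   as `data`, or `NULL`.
#' @param intervals `data.frame(task, start_s, end_s)` or `NULL`.
#' @param condition audio condition label.
#' @param truth optional list of planted ground truth (synthetic data only).
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs = 256, gyro = NULL, intervals = NULL,
                          condition = NA_character_, truth = NULL) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == 4, fs > 0)
  colnames(data) <- c("AF7", "AF8", "TP9", "TP10")
  if (!is.null(gyro)) {
    gyro <- as.matrix(gyro)
    stopifnot(ncol(gyro) == 3, nrow(gyro) == nrow(data))
    colnames(gyro) <- c("gyro_x", "gyro_y", "gyro_z")
  }
  if (!is.null(intervals)) {
    stopifnot(all(c("task", "start_s", "end_s") %in% names(intervals)))
    dur <- nrow(data) / fs
    if (any(intervals$start_s < 0) || any(intervals$end_s > dur + 1e-9)) {
      stop("task intervals must lie within [0, duration]")
    }
  }
  structure(list(data = data, fs = fs, gyro = gyro, intervals = intervals,
                 condition = condition, truth = truth),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x 4 channels @ %g Hz (%.1f s), condition: %s\n",
              nrow(x$data), x$fs, nrow(x$data) / x$fs, x$condition))
  invisible(x)
}

duration_s <- function(rec) nrow(rec$data) / rec$fs

#' Generate a synthetic EEG recording with planted focus coupling
#'
#' Synthesizes 4-channel EEG whose alpha-band (10 Hz) amplitude decreases and
#' beta-band (20 Hz) amplitude increases monotonically with a latent focus
#' profile, on top of 1/f background and sensor noise, with stereotyped blink
#' transients on the frontal channels and gyroscope motion episodes. All
#' randomness is a pure function of `seed`.
#'
#' The coupling is `alpha_amp * (1 - coupling * f(t))` and
#' `beta_amp * (1 - coupling + coupling * f(t))` for focus `f(t)` in `[0, 1]`,
#' so band powers carry a monotone planted relation that the feature battery
#' can recover.
#'
#' @param duration_s recording length in seconds (> 0).
#' @param profile a [focus_profile()].
#' @param blink_rate blink events per minute (>= 0).
#' @param motion_rate motion episodes per minute (>= 0).
#' @param seed integer seed.
#' @param fs sampling rate (Hz).
#' @param background_sd SD of the 1/f background (uV).
#' @param sensor_sd SD of white sensor noise (uV).
#' @param alpha_amp,beta_amp,theta_amp,delta_amp oscillation amplitudes (uV).
#' @param coupling planted coupling strength in `[0, 1]`.
#' @param condition audio condition label carried on the recording.
#' @param intervals optional task interval table.
#' @return an [eeg_recording()]; `$truth` holds the profile sampled at `fs`,
#'   blink times, and motion episode spans.
#' @examples
#' p <- focus_profile(c(0, 10), c(0.2, 0.8))
#' rec <- generate_eeg(10, p, seed = 1)
#' @export
generate_eeg <- function(duration_s, profile, blink_rate = 16,
                         motion_rate = 1, seed = NULL, fs = 256,
                         background_sd = 10, sensor_sd = 2,
                         alpha_amp = 12, beta_amp = 10,
                         theta_amp = 4, delta_amp = 6,
                         coupling = 0.8, condition = NA_character_,
                         intervals = NULL) {
  stopifnot(duration_s > 0, blink_rate >= 0, motion_rate >= 0)
  if (!inherits(profile, "focus_profile")) stop("profile must be a focus_profile")
  n <- round(fs * duration_s)
  t <- (seq_len(n) - 1) / fs
  f <- profile_at(profile, t)

  with_seed(seed, {
    a_amp <- alpha_amp * (1 - coupling * f)
    b_amp <- beta_amp * (1 - coupling + coupling * f)
    data <- matrix(0, n, 4)
    for (ch in 1:4) {
      ph <- stats::runif(4, 0, 2 * pi)
      x <- a_amp * sin(2 * pi * 10 * t + ph[1]) +
        b_amp * sin(2 * pi * 20 * t + ph[2]) +
        theta_amp * sin(2 * pi * 6 * t + ph[3]) +
        delta_amp * sin(2 * pi * 2 * t + ph[4])
      if (background_sd > 0) x <- x + background_sd * pink_noise(n)
      if (sensor_sd > 0) x <- x + sensor_sd * stats::rnorm(n)
      data[, ch] <- x
    }

    # Blinks: ~400 ms frontal transients, amplitude well above background.
    n_blinks <- stats::rpois(1, blink_rate * duration_s / 60)
    blink_times <- sort(stats::runif(n_blinks, 0.3, max(0.3, duration_s - 0.3)))
    # enforce a refractory gap so planted events are countable
    if (n_blinks > 1) {
      keep <- c(TRUE, diff(blink_times) > 0.5)
      blink_times <- blink_times[keep]
    }
    for (bt in blink_times) {
      idx <- which(abs(t - bt) <= 0.2)
      bump <- 130 * exp(-((t[idx] - bt)^2) / (2 * 0.06^2))
      data[idx, 1] <- data[idx, 1] + bump
      data[idx, 2] <- data[idx, 2] + 0.9 * bump
    }

    # Gyroscope: quiet baseline plus planted movement episodes.
    gyro <- matrix(stats::rnorm(3 * n, 0, 0.7), n, 3)
    n_mov <- stats::rpois(1, motion_rate * duration_s / 60)
    episodes <- NULL
    if (n_mov > 0) {
      starts <- sort(stats::runif(n_mov, 0, duration_s))
      lens <- pmax(1, stats::rexp(n_mov, 1 / 5))
      amps <- stats::runif(n_mov, 15, 60)
      episodes <- data.frame(start_s = starts,
                             end_s = pmin(duration_s, starts + lens),
                             amp = amps)
      for (i in seq_len(n_mov)) {
        idx <- which(t >= episodes$start_s[i] & t < episodes$end_s[i])
        if (!length(idx)) next
        wob <- amps[i] * sin(2 * pi * 2 * t[idx] + stats::runif(1, 0, 2 * pi))
        gyro[idx, ] <- gyro[idx, ] + cbind(wob, 0.6 * wob, 0.3 * wob)
      }
    }

    eeg_recording(data, fs = fs, gyro = gyro, intervals = intervals,
                  condition = condition,
                  truth = list(profile = f, blink_times = blink_times,
                               motion_episodes = episodes))
  })
}
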