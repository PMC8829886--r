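#' Band-pass and notch filter an EEG recording
#'
#' Applies a zero-phase 0.5-70 Hz band-pass and a 60 Hz notch independently
#' per channel, preserving length. The band-pass is a frequency-domain
#' filter with raised-cosine transition bands (0.25 Hz at the low edge, 5 Hz
#' at the high edge) applied to the reflection-padded signal: at a 0.5 Hz
#' corner this stays numerically exact and idempotent where an IIR design is
#' neither. The notch is a quality-30 biquad run forward-backward
#' (`signal::filtfilt`).
#'
#' @param rec an [eeg_recording()].
#' @param band passband corners in Hz.
#' @param notch_hz line frequency to remove.
#' @param notch_q notch quality factor.
#' @return the filtered recording (same class, gyro/intervals untouched).
#' @export
filter_recording <- function(rec, band = c(0.5, 70), notch_hz = 60,
                             notch_q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs <= 2 * band[2]) {
    stop(sprintf("sampling rate %g Hz too low for a %g Hz passband edge",
                 fs, band[2]))
  }
  nt <- design_notch(notch_hz, fs, notch_q)
  out <- rec
  for (ch in 1:4) {
    x <- fft_bandpass(rec$data[, ch], fs, band[1], band[2])
    out$data[, ch] <- signal::filtfilt(signal::Arma(nt$b, nt$a), x)
  }
  out
}

# Zero-phase band-pass via FFT gain mask with raised-cosine transitions.
# The signal is reflection-padded (up to pad_s on each side) to suppress
# wrap-around ringing at the record edges.
fft_bandpass <- function(x, fs, low, high, trans_lo = 0.25, trans_hi = 5,
                         pad_s = 10) {
  n <- length(x)
  pad <- min(n - 1L, round(pad_s * fs))
  xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  np <- length(xp)
  f <- pmin(0:(np - 1), np - (0:(np - 1))) * fs / np
  ramp_up <- function(f, f0, tw) { # 0 below f0 - tw, 1 above f0
    g <- (f - (f0 - tw)) / tw
    0.5 - 0.5 * cos(pi * pmin(1, pmax(0, g)))
  }
  gain <- ramp_up(f, low, trans_lo) * (1 - ramp_up(f, high + trans_hi, trans_hi))
  y <- Re(stats::fft(stats::fft(xp) * gain, inverse = TRUE)) / np
  y[(pad + 1):(pad + n)]
}

# RBJ biquad notch coefficients.
design_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Segment a recording with a sliding window
#'
#' Slides a `window_s` window with stride `stride_s` over the recording
#' (defaults 5 s / 200 ms, i.e. 96% overlap, one segment per 200 ms giving a
#' 5 Hz decoded trace). Returns an index table rather than materialized
#' windows; use [get_segment()] to extract one window's samples.
#'
#' Each row carries the task the window starts in (from the recording's
#' interval table), its motion state from the gyroscope, the number of blink
#' events detected inside it, and the gating decision: calibration-task
#' segments with non-static motion are excluded, Preferred-Task segments are
#' always retained.
#'
#' @param rec an [eeg_recording()] (filtered or raw).
#' @param window_s window length in seconds.
#' @param stride_s stride in seconds.
#' @return `data.frame(segment_id, start_s, task, motion, blink_count,
#'   retained)`; zero rows if the recording is shorter than one window.
#' @examples
#' p <- focus_profile(c(0, 12), c(0.5, 0.5))
#' rec <- generate_eeg(12, p, seed = 1)
#' nrow(segment_recording(rec)) # floor((12 - 5) / 0.2) + 1
#' @export
segment_recording <- function(rec, window_s = 5, stride_s = 0.2) {
  stopifnot(inherits(rec, "eeg_recording"), window_s > 0, stride_s > 0)
  dur <- duration_s(rec)
  if (dur < window_s) {
    return(data.frame(segment_id = integer(), start_s = numeric(),
                      task = character(), motion = character(),
                      blink_count = integer(), retained = logical()))
  }
  n_seg <- floor((dur - window_s) / stride_s + 1e-9) + 1
  start_s <- (seq_len(n_seg) - 1) * stride_s
  task <- assign_task(start_s, rec$intervals)
  motion <- segment_motion(rec, start_s, window_s)
  blink_count <- segment_blinks(rec, start_s, window_s)
  retained <- task == "preferred" | is.na(task) | motion == "static"
  data.frame(segment_id = seq_len(n_seg), start_s = start_s, task = task,
             motion = motion, blink_count = blink_count, retained = retained)
}

assign_task <- function(start_s, intervals) {
  if (is.null(intervals)) return(rep(NA_character_, length(start_s)))
  task <- rep(NA_character_, length(start_s))
  for (i in seq_len(nrow(intervals))) {
    sel <- start_s >= intervals$start_s[i] & start_s < intervals$end_s[i]
    task[sel] <- intervals$task[i]
  }
  task
}

#' Extract one segment's samples
#'
#' @param rec an [eeg_recording()].
#' @param start_s window start in seconds.
#' @param window_s window length in seconds.
#' @return samples x 4 matrix.
#' @export
get_segment <- function(rec, start_s, window_s = 5) {
  i0 <- round(start_s * rec$fs) + 1L
  i1 <- i0 + round(window_s * rec$fs) - 1L
  stopifnot(i1 <= nrow(rec$data))
  rec$data[i0:i1, , drop = FALSE]
}

#' Headband placement quality control
#'
#' Flags a channel as misplaced when the standard deviation of its raw
#' (pre-filter) signal exceeds 500 uV; the comparison is strict, so SD exactly
#' 500 passes.
#'
#' @param rec the raw [eeg_recording()].
#' @param sd_limit threshold in uV.
#' @return named character vector per channel: `"pass"` or `"misplaced"`.
#' @export
qc_headband <- function(rec, sd_limit = 500) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2) stop("empty channel: cannot compute SD")
  sds <- apply(rec$data, 2, stats::sd)
  out <- ifelse(sds > sd_limit, "misplaced", "pass")
  names(out) <- colnames(rec$data)
  out
}

# Gyro RMS thresholds separating motion states (deg/s). The study never
# quantifies "substantial movement"; these are the package's operating points.
MOTION_THRESHOLDS <- c(static = 5, high = 30)

#' Motion state of segments
#'
#' Classifies each window from the RMS of the 3-axis gyroscope over the
#' window: `static` below 5 deg/s, `high` at or above 30 deg/s, `medium`
#' in between. With no gyroscope data every segment is `static` (with a
#' warning).
#'
#' @param rec an [eeg_recording()].
#' @param start_s vector of window starts (s).
#' @param window_s window length (s).
#' @return character vector of states.
#' @export
segment_motion <- function(rec, start_s, window_s = 5) {
  if (is.null(rec$gyro)) {
    warning("no gyroscope data; treating all segments as static")
    return(rep("static", length(start_s)))
  }
  msq <- rowMeans(rec$gyro^2)
  cs <- c(0, cumsum(msq))
  fs <- rec$fs
  wlen <- round(window_s * fs)
  i0 <- round(start_s * fs)
  rms <- sqrt((cs[pmin(i0 + wlen, length(cs))] - cs[i0 + 1]) / wlen)
  ifelse(rms < MOTION_THRESHOLDS["static"], "static",
         ifelse(rms < MOTION_THRESHOLDS["high"], "medium", "high"))
}

#' Detect blink events on the frontal channels
#'
#' Matched peak detection: the frontal-channel mean is band-passed to
#' 1-10 Hz, and samples exceeding 3x the robust SD (MAD) are grouped into
#' events with a 300 ms refractory period.
#'
#' @param rec an [eeg_recording()].
#' @param threshold_k multiple of the robust SD.
#' @param refractory_s minimum spacing between events.
#' @return numeric vector of blink times in seconds.
#' @export
detect_blinks <- function(rec, threshold_k = 3, refractory_s = 0.3) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  frontal <- rowMeans(rec$data[, c("AF7", "AF8")])
  bp <- signal::butter(2, c(1, 10) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, frontal)
  thr <- threshold_k * stats::mad(x)
  if (thr <= 0) return(numeric())
  above <- which(x > thr)
  if (!length(above)) return(numeric())
  gaps <- which(diff(above) > refractory_s * fs)
  starts <- above[c(1, gaps + 1)]
  ends <- above[c(gaps, length(above))]
  # peak time within each suprathreshold group
  vapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    (seg[which.max(x[seg])] - 1) / fs
  }, numeric(1))
}

#' Blink rate of a recording
#'
#' @param rec an [eeg_recording()].
#' @param ... passed to [detect_blinks()].
#' @return blinks per minute.
#' @export
blink_rate <- function(rec, ...) {
  length(detect_blinks(rec, ...)) / (duration_s(rec) / 60)
}

segment_blinks <- function(rec, start_s, window_s = 5) {
  bt <- detect_blinks(rec)
  vapply(start_s, function(s0) {
    sum(bt >= s0 & bt < s0 + window_s)
  }, integer(1))
}
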