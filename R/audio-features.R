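AUDIO_BASE_FEATURES <- c(
  "zcr", "energy", "energy_entropy", "spectral_centroid", "spectral_spread",
  "spectral_entropy", "spectral_flux", "spectral_rolloff",
  paste0("mfcc_", 1:13), paste0("chroma_", 1:12), "chroma_std"
)

#' Schema of the 136 aggregated sound properties
#'
#' 34 short-time descriptors (zero-crossing rate, energy, entropy of energy,
#' spectral centroid/spread/entropy/flux/rolloff, 13 MFCCs, 12 chroma
#' coefficients, chroma deviation) plus their first-order frame deltas give
#' 68 frame features; the per-30 s mean and SD of each give 136 properties.
#'
#' @return `data.frame(name, base, delta, stat)` with 136 rows.
#' @export
audio_feature_schema <- function() {
  frame <- c(AUDIO_BASE_FEATURES, paste0("delta_", AUDIO_BASE_FEATURES))
  data.frame(
    name = c(paste0(frame, "_mean"), paste0(frame, "_sd")),
    base = rep(rep(AUDIO_BASE_FEATURES, 2), 2),
    delta = rep(rep(c(FALSE, TRUE), each = 34), 2),
    stat = rep(c("mean", "sd"), each = 68)
  )
}

mel_filterbank <- function(n_filters, nfft_bins, fs) {
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(mel(0), mel(fs / 2), length.out = n_filters + 2))
  freqs <- (0:(nfft_bins - 1)) * (fs / 2) / (nfft_bins - 1)
  fb <- matrix(0, n_filters, nfft_bins)
  for (i in seq_len(n_filters)) {
    lo <- pts[i]; ce <- pts[i + 1]; hi <- pts[i + 2]
    up <- freqs >= lo & freqs <= ce
    dn <- freqs > ce & freqs <= hi
    fb[i, up] <- (freqs[up] - lo) / max(ce - lo, 1e-12)
    fb[i, dn] <- (hi - freqs[dn]) / max(hi - ce, 1e-12)
  }
  fb
}

dct_matrix <- function(k, n) {
  m <- outer(seq_len(k) - 1, seq_len(n) - 0.5, function(i, j) {
    cos(pi * i * j / n)
  })
  m * sqrt(2 / n)
}

#' Short-time audio feature matrix
#'
#' Decomposes a clip into 50 ms frames sliding by 25 ms and computes 68
#' features per frame: 34 base descriptors and their first-order frame
#' deltas. Spectral descriptors use a Hamming-windowed magnitude spectrum;
#' centroid, spread and rolloff are reported in Hz; spectral entropy is the
#' Shannon entropy (bits) of the power in 10 sub-bands; chroma is the
#' pitch-class energy profile normalized by total spectral energy.
#'
#' @param clip an [audio_clip()].
#' @param frame_s frame length in seconds (0.050).
#' @param hop_s hop between frame starts in seconds (0.025).
#' @return frames x 68 matrix with attributes `times` (frame starts, s),
#'   `duration_s`, `song_id`, `genre`, `focus_target`.
#' @export
short_time_audio_features <- function(clip, frame_s = 0.050, hop_s = 0.025) {
  stopifnot(inherits(clip, "audio_clip"))
  fs <- clip$sample_rate
  x <- clip$samples
  nwin <- floor(frame_s * fs)
  hop <- floor(hop_s * fs)
  if (length(x) < nwin) stop("clip shorter than one frame")
  n_frames <- floor((length(x) - nwin) / hop) + 1L
  idx <- outer(seq_len(nwin), (seq_len(n_frames) - 1L) * hop, `+`)
  F <- matrix(x[idx], nwin, n_frames)

  zcr <- colSums(F[-1, , drop = FALSE] * F[-nwin, , drop = FALSE] < 0) /
    (nwin - 1)
  energy <- colMeans(F^2)

  # entropy of energy over 10 sub-blocks of the frame
  nb <- 10L
  bl <- floor(nwin / nb)
  sub <- F[seq_len(nb * bl), , drop = FALSE]
  dim(sub) <- c(bl, nb, n_frames)
  be <- colSums(array(sub^2, c(bl, nb, n_frames)), dims = 1) # nb x frames
  tot <- colSums(be)
  pe <- sweep(be, 2, pmax(tot, 1e-300), "/")
  energy_entropy <- -colSums(ifelse(pe > 0, pe * log2(pe), 0))
  energy_entropy[tot <= 0] <- 0

  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1)) # Hamming
  S <- Mod(stats::mvfft(F * w))[1:(floor(nwin / 2) + 1L), , drop = FALSE]
  nf <- nrow(S)
  freqs <- (0:(nf - 1)) * fs / nwin
  P <- S^2
  Psum <- pmax(colSums(P), 1e-300)
  # centroid/spread over the power spectrum: sidelobe leakage of the taper
  # then contributes negligibly, so a pure tone's centroid sits on its pitch
  centroid <- colSums(freqs * P) / Psum
  centroid[colSums(P) == 0] <- 0
  dev2 <- (matrix(freqs, nf, n_frames) - rep(centroid, each = nf))^2
  spread <- sqrt(pmax(colSums(dev2 * P) / Psum, 0))

  # spectral entropy over 10 sub-bands
  sb <- floor(nf / nb)
  Pb <- P[seq_len(nb * sb), , drop = FALSE]
  dim(Pb) <- c(sb, nb, n_frames)
  bp <- colSums(array(Pb, c(sb, nb, n_frames)), dims = 1)
  pp <- sweep(bp, 2, pmax(colSums(bp), 1e-300), "/")
  spec_entropy <- -colSums(ifelse(pp > 0, pp * log2(pp), 0))
  spec_entropy[colSums(bp) <= 0] <- 0

  Pn <- sweep(P, 2, Psum, "/")
  flux <- c(0, colSums((Pn[, -1, drop = FALSE] -
                          Pn[, -n_frames, drop = FALSE])^2))
  if (n_frames == 1L) flux <- 0

  cum <- apply(P, 2, cumsum)
  rolloff <- freqs[max.col(t(cum >= rep(0.90 * Psum, each = nf)),
                           ties.method = "first")]
  rolloff[colSums(P) == 0] <- 0

  fb <- mel_filterbank(26, nf, fs)
  melE <- log(pmax(fb %*% P, 1e-300))
  mfcc <- dct_matrix(13, 26) %*% melE

  pitch_class <- rep(NA_integer_, nf)
  aud <- freqs >= 27.5
  pitch_class[aud] <- (round(69 + 12 * log2(freqs[aud] / 440))) %% 12
  chroma <- matrix(0, 12, n_frames)
  for (k in 0:11) {
    sel <- which(pitch_class == k)
    if (length(sel)) chroma[k + 1, ] <- colSums(P[sel, , drop = FALSE])
  }
  chroma <- sweep(chroma, 2, Psum, "/")
  cmu <- colMeans(chroma)
  chroma_std <- sqrt(pmax(colSums(chroma^2) - 12 * cmu^2, 0) / 11)

  base <- rbind(zcr, energy, energy_entropy, centroid, spread, spec_entropy,
                flux, rolloff, mfcc, chroma, chroma_std)
  rownames(base) <- AUDIO_BASE_FEATURES
  delta <- cbind(0, base[, -1, drop = FALSE] - base[, -n_frames, drop = FALSE])
  if (n_frames == 1L) delta <- base * 0
  rownames(delta) <- paste0("delta_", AUDIO_BASE_FEATURES)
  out <- t(rbind(base, delta))
  attr(out, "times") <- (seq_len(n_frames) - 1L) * hop / fs
  attr(out, "duration_s") <- length(x) / fs
  attr(out, "song_id") <- clip$song_id
  attr(out, "genre") <- clip$genre
  attr(out, "focus_target") <- clip$focus_target
  out
}

#' Aggregate frame features to 30 s sound properties
#'
#' Computes the mean and SD of each of the 68 frame features over
#' consecutive non-overlapping 30 s windows aligned to the clip start,
#' yielding exactly 136 property columns per window. A trailing partial
#' window is dropped.
#'
#' @param frames a [short_time_audio_features()] matrix.
#' @param window_s aggregation window in seconds (30).
#' @return data frame: `song_id`, `genre`, `focus_target`, `window`,
#'   `start_s`, then the 136 property columns; zero rows (with a warning)
#'   when the clip is shorter than one window.
#' @export
aggregate_audio_features <- function(frames, window_s = 30) {
  times <- attr(frames, "times")
  dur <- attr(frames, "duration_s")
  n_win <- floor(dur / window_s)
  sch <- audio_feature_schema()
  if (n_win < 1) {
    warning("clip shorter than one aggregation window")
    out <- as.data.frame(matrix(numeric(), 0, 136,
                                dimnames = list(NULL, sch$name)))
    return(cbind(data.frame(song_id = character(), genre = character(),
                            focus_target = numeric(), window = integer(),
                            start_s = numeric()), out))
  }
  rows <- lapply(seq_len(n_win), function(wdx) {
    sel <- times >= (wdx - 1) * window_s & times < wdx * window_s
    sub <- frames[sel, , drop = FALSE]
    v <- c(colMeans(sub), col_sds(sub))
    names(v) <- sch$name
    as.data.frame(t(v))
  })
  cbind(
    data.frame(song_id = attr(frames, "song_id") %||% NA_character_,
               genre = attr(frames, "genre") %||% NA_character_,
               focus_target = attr(frames, "focus_target") %||% NA_real_,
               window = seq_len(n_win),
               start_s = (seq_len(n_win) - 1) * window_s),
    do.call(rbind, rows)
  )
}

#' Resample a clip by linear interpolation
#'
#' Frame features (mel and chroma banks in particular) assume a common
#' sample rate; clips at other rates are resampled before framing.
#'
#' @param clip an [audio_clip()].
#' @param rate target rate in Hz.
#' @return an [audio_clip()] at `rate`.
#' @export
resample_clip <- function(clip, rate = 22050) {
  if (clip$sample_rate == rate) return(clip)
  n_out <- round(length(clip$samples) / clip$sample_rate * rate)
  t_out <- (seq_len(n_out) - 1) / rate
  t_in <- (seq_along(clip$samples) - 1) / clip$sample_rate
  audio_clip(stats::approx(t_in, clip$samples, xout = t_out, rule = 2)$y,
             sample_rate = rate, song_id = clip$song_id, genre = clip$genre,
             focus_target = clip$focus_target)
}

#' Audio feature table for a set of clips
#'
#' Runs [short_time_audio_features()] and [aggregate_audio_features()] over a
#' list of clips and stacks the per-window rows.
#'
#' @param clips list of [audio_clip()]s.
#' @param frame_s,hop_s,window_s framing and aggregation parameters.
#' @param sample_rate common rate clips are resampled to before framing.
#' @return stacked data frame (one row per complete 30 s window).
#' @export
audio_feature_table <- function(clips, frame_s = 0.050, hop_s = 0.025,
                                window_s = 30, sample_rate = 22050) {
  do.call(rbind, lapply(clips, function(cl) {
    aggregate_audio_features(
      short_time_audio_features(resample_clip(cl, sample_rate),
                                frame_s, hop_s), window_s)
  }))
}
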