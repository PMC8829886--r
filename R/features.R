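#' EEG frequency bands
#'
#' The seven analysis bands in Hz: delta (0.5-4), theta (4-8), alpha
#' (8-12.5), beta (12.5-30), low gamma (30-47), high gamma (52-70, skipping
#' the 47-52 Hz strip around the line-noise region) and broad gamma (30-70).
#' Band edges are inclusive-low / exclusive-high on the frequency grid.
#' @export
BANDS <- data.frame(
  band = c("delta", "theta", "alpha", "beta", "gamma1", "gamma2", "gamma"),
  low = c(0.5, 4, 8, 12.5, 30, 52, 30),
  high = c(4, 8, 12.5, 30, 47, 70, 70)
)

CHANNELS <- c("AF7", "AF8", "TP9", "TP10")
CHANNEL_PAIRS <- utils::combn(CHANNELS, 2)
TD_STATS <- c("mean", "sd", "skewness", "kurtosis", "entropy", "zerocross")
INTERACTIONS <- c("alpha_delta", "beta_theta", "theta_alpha", "engagement")

#' Feature schema for the 124-feature EEG battery
#'
#' Stable name, group, channel and band of every feature, in extraction
#' order: 28 band powers, 14 symmetric-channel power ratios, 16 spectral
#' interactions, 42 pairwise band correlations, 24 time-domain statistics.
#'
#' @return `data.frame(name, group, channel, band)` with 124 rows.
#' @export
feature_schema <- function() {
  if (!is.null(.nf_cache$schema)) {
    return(.nf_cache$schema)
  }
  .nf_cache$schema <- build_feature_schema()
  .nf_cache$schema
}

.nf_cache <- new.env(parent = emptyenv())

build_feature_schema <- function() {
  pow <- expand.grid(band = BANDS$band, channel = CHANNELS,
                     stringsAsFactors = FALSE)[, 2:1]
  pow <- data.frame(name = paste0("pow_", pow$channel, "_", pow$band),
                    group = "power", channel = pow$channel, band = pow$band)
  pairs <- c("AF7AF8", "TP9TP10")
  rat <- expand.grid(band = BANDS$band, channel = pairs,
                     stringsAsFactors = FALSE)[, 2:1]
  rat <- data.frame(name = paste0("ratio_", rat$channel, "_", rat$band),
                    group = "symmetric_ratio", channel = rat$channel,
                    band = rat$band)
  ix <- expand.grid(band = INTERACTIONS, channel = CHANNELS,
                    stringsAsFactors = FALSE)[, 2:1]
  ix <- data.frame(name = paste0("ix_", ix$channel, "_", ix$band),
                   group = "interaction", channel = ix$channel, band = ix$band)
  cp <- apply(CHANNEL_PAIRS, 2, paste, collapse = "_")
  cor <- expand.grid(band = BANDS$band, channel = cp,
                     stringsAsFactors = FALSE)[, 2:1]
  cor <- data.frame(name = paste0("corr_", cor$channel, "_", cor$band),
                    group = "correlation", channel = cor$channel,
                    band = cor$band)
  td <- expand.grid(band = TD_STATS, channel = CHANNELS,
                    stringsAsFactors = FALSE)[, 2:1]
  td <- data.frame(name = paste0("td_", td$channel, "_", td$band),
                   group = "time_domain", channel = td$channel, band = td$band)
  rbind(pow, rat, ix, cor, td)
}

#' Band powers of one EEG segment
#'
#' Welch spectrum per channel (1 s Hann sub-windows, 50% overlap), averaged
#' within each of the seven bands: 4 channels x 7 bands = 28 features.
#'
#' @param seg samples x 4 matrix (one 5 s window).
#' @param fs sampling rate (Hz).
#' @return named numeric vector of length 28 (channel-major order).
#' @export
band_powers <- function(seg, fs = 256) {
  seg <- as.matrix(seg)
  stopifnot(ncol(seg) == 4)
  out <- numeric(0)
  for (ch in 1:4) {
    psd <- welch_psd(seg[, ch], fs)
    out <- c(out, vapply(seq_len(nrow(BANDS)), function(b) {
      band_mean(psd, BANDS$low[b], BANDS$high[b])
    }, numeric(1)))
  }
  names(out) <- feature_schema()$name[1:28]
  out
}

# Positional lookup into the channel-major 28-vector of band powers.
get_power <- function(powers, ch, band) {
  powers[[(match(ch, CHANNELS) - 1L) * 7L + match(band, BANDS$band)]]
}

safe_ratio <- function(num, den) {
  if (!is.finite(den) || den == 0) {
    structure(0, flagged = TRUE)
  } else {
    num / den
  }
}

#' Symmetric-channel power ratios
#'
#' Per-band power ratio between spatially symmetric channels (frontal
#' AF7/AF8 and temporal TP9/TP10): 2 pairs x 7 bands = 14 features. A zero
#' denominator yields 0 with the feature name recorded in the `"flags"`
#' attribute.
#'
#' @param powers output of [band_powers()].
#' @return named numeric vector of length 14.
#' @export
symmetric_power_ratios <- function(powers) {
  sch <- feature_schema()
  nm <- sch$name[sch$group == "symmetric_ratio"]
  pairs <- list(AF7AF8 = c("AF7", "AF8"), TP9TP10 = c("TP9", "TP10"))
  out <- numeric(0)
  flags <- character(0)
  for (pr in names(pairs)) {
    for (b in BANDS$band) {
      den <- get_power(powers, pairs[[pr]][2], b)
      num <- get_power(powers, pairs[[pr]][1], b)
      v <- safe_ratio(num, den)
      if (isTRUE(attr(v, "flagged"))) flags <- c(flags, paste0("ratio_", pr, "_", b))
      out <- c(out, as.numeric(v))
    }
  }
  names(out) <- nm
  if (length(flags)) attr(out, "flags") <- flags
  out
}

#' Spectral interaction features
#'
#' Per-channel band-power ratios alpha/delta, beta/theta, theta/alpha and the
#' engagement index beta / (alpha + theta): 4 channels x 4 interactions = 16
#' features. Zero denominators yield 0 and are flagged.
#'
#' @param powers output of [band_powers()].
#' @return named numeric vector of length 16.
#' @export
spectral_interactions <- function(powers) {
  sch <- feature_schema()
  nm <- sch$name[sch$group == "interaction"]
  out <- numeric(0)
  flags <- character(0)
  for (ch in CHANNELS) {
    a <- get_power(powers, ch, "alpha")
    d <- get_power(powers, ch, "delta")
    th <- get_power(powers, ch, "theta")
    be <- get_power(powers, ch, "beta")
    vals <- list(safe_ratio(a, d), safe_ratio(be, th), safe_ratio(th, a),
                 safe_ratio(be, a + th))
    for (i in seq_along(vals)) {
      if (isTRUE(attr(vals[[i]], "flagged"))) {
        flags <- c(flags, paste0("ix_", ch, "_", INTERACTIONS[i]))
      }
    }
    out <- c(out, vapply(vals, as.numeric, numeric(1)))
  }
  names(out) <- nm
  if (length(flags)) attr(out, "flags") <- flags
  out
}

# Zero out of band FFT bins of a multichannel matrix; returns filtered matrix.
# X may be a precomputed mvfft of x.
band_filter_fft <- function(x, fs, low, high, X = NULL) {
  n <- nrow(x)
  if (is.null(X)) X <- stats::mvfft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  mask <- f >= low & f < high
  Re(stats::mvfft(X * mask, inverse = TRUE)) / n
}

#' Pairwise inter-channel correlations per band
#'
#' Band-passes each channel (ideal FFT-mask filter) to each of the seven
#' bands and computes Pearson correlations over all 6 unordered channel
#' pairs: 6 pairs x 7 bands = 42 features. A zero-variance channel in a band
#' gives correlation 0 (flagged).
#'
#' @param seg samples x 4 matrix.
#' @param fs sampling rate (Hz).
#' @return named numeric vector of length 42 (band within pair order follows
#'   [feature_schema()]).
#' @export
pairwise_band_correlations <- function(seg, fs = 256) {
  seg <- as.matrix(seg)
  X <- stats::mvfft(seg)
  out <- numeric(0)
  for (b in seq_len(nrow(BANDS))) {
    xb <- band_filter_fft(seg, fs, BANDS$low[b], BANDS$high[b], X = X)
    cc <- suppressWarnings(stats::cor(xb))
    vals <- cc[lower.tri(cc)]
    vals[!is.finite(vals)] <- 0
    out <- c(out, vals)
  }
  # reorder to pair-major (schema order: per pair, all bands)
  m <- matrix(out, nrow = 6) # [pair, band]
  out <- as.numeric(t(m))
  names(out) <- feature_schema()$name[59:100]
  out
}

signal_entropy <- function(x, bins = 64) {
  if (stats::sd(x) == 0) return(0)
  h <- tabulate(cut(x, bins, labels = FALSE), nbins = bins)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log2(p))
}

zero_crossings <- function(x) {
  sum(x[-1] * x[-length(x)] < 0)
}

#' Time-domain features
#'
#' Per channel: mean, SD, skewness, excess kurtosis, Shannon entropy of a
#' 64-bin amplitude histogram (bits), and zero-crossing count:
#' 4 channels x 6 = 24 features.
#'
#' @param seg samples x 4 matrix.
#' @return named numeric vector of length 24.
#' @export
time_domain_features <- function(seg) {
  seg <- as.matrix(seg)
  out <- numeric(0)
  for (ch in 1:4) {
    x <- seg[, ch]
    s <- stats::sd(x)
    out <- c(out, mean(x), s,
             if (s == 0) 0 else e1071::skewness(x),
             if (s == 0) 0 else e1071::kurtosis(x),
             signal_entropy(x), zero_crossings(x))
  }
  names(out) <- feature_schema()$name[101:124]
  out
}

#' Extract the full 124-feature vector of one segment
#'
#' Concatenates the five groups in schema order: band powers (28), symmetric
#' power ratios (14), spectral interactions (16), pairwise band correlations
#' (42) and time-domain statistics (24). Deterministic for a given segment.
#'
#' @param seg samples x 4 matrix (a 5 s window at 256 Hz).
#' @param fs sampling rate (Hz).
#' @return named numeric vector of length 124.
#' @export
extract_features <- function(seg, fs = 256) {
  powers <- band_powers(seg, fs)
  out <- c(powers,
           symmetric_power_ratios(powers),
           spectral_interactions(powers),
           pairwise_band_correlations(seg, fs),
           time_domain_features(seg))
  stopifnot(length(out) == 124)
  out
}

#' Feature matrix of a recording
#'
#' Extracts the 124-feature battery for every segment in the index table.
#' Band-filtered copies of the whole recording are computed once so the 42
#' correlation features cost one small cross-product per window.
#'
#' @param rec a filtered [eeg_recording()].
#' @param segments segment table from [segment_recording()]; defaults to
#'   segmenting `rec` at 5 s / 200 ms.
#' @param window_s window length (s).
#' @return numeric matrix, segments x 124, rows aligned with `segments`.
#' @export
feature_matrix <- function(rec, segments = NULL, window_s = 5) {
  if (is.null(segments)) segments <- segment_recording(rec, window_s)
  fs <- rec$fs
  wlen <- round(window_s * fs)
  sch <- feature_schema()
  out <- matrix(NA_real_, nrow(segments), 124,
                dimnames = list(NULL, sch$name))
  if (!nrow(segments)) return(out)

  X <- stats::mvfft(rec$data)
  bandsig <- lapply(seq_len(nrow(BANDS)), function(b) {
    band_filter_fft(rec$data, fs, BANDS$low[b], BANDS$high[b], X = X)
  })
  corr_names <- sch$name[sch$group == "correlation"]

  for (i in seq_len(nrow(segments))) {
    i0 <- round(segments$start_s[i] * fs) + 1L
    idx <- i0:(i0 + wlen - 1L)
    seg <- rec$data[idx, , drop = FALSE]
    powers <- band_powers(seg, fs)
    corrs <- numeric(0)
    for (b in seq_len(nrow(BANDS))) {
      cc <- suppressWarnings(stats::cor(bandsig[[b]][idx, , drop = FALSE]))
      vals <- cc[lower.tri(cc)]
      vals[!is.finite(vals)] <- 0
      corrs <- c(corrs, vals)
    }
    corrs <- as.numeric(t(matrix(corrs, nrow = 6)))
    names(corrs) <- corr_names
    out[i, ] <- c(powers, symmetric_power_ratios(powers),
                  spectral_interactions(powers), corrs,
                  time_domain_features(seg))
  }
  out
}

#' Trim extreme feature values
#'
#' Winsorizes each feature column to mean +/- `k` standard deviations, both
#' computed on the input column (the processing unit is one participant's
#' session unless the caller pools differently). Keeping clipped rather than
#' dropped values leaves the 5 Hz trace gap-free.
#'
#' @param x segments x features matrix (or data.frame of numerics).
#' @param k SD multiple defining extreme values.
#' @return matrix of the same shape with all values inside the boundaries.
#' @export
trim_outliers <- function(x, k = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 2) {
    warning("fewer than 2 rows; returning input unchanged")
    return(x)
  }
  mu <- colMeans(x)
  sd <- col_sds(x)
  lo <- mu - k * sd
  hi <- mu + k * sd
  for (j in seq_len(ncol(x))) {
    x[, j] <- pmin(pmax(x[, j], lo[j]), hi[j])
  }
  x
}
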