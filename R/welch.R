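#' Welch power spectral density estimate
#'
#' Averages one-sided periodograms of Hann-tapered sub-windows (default 1 s
#' with 50% overlap, giving 0.5 Hz native resolution with 1 Hz bin spacing --
#' enough to resolve the 0.5 Hz low band edge over a 5 s segment).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param window_s sub-window length (s).
#' @param overlap fractional overlap of consecutive sub-windows.
#' @return list with `freq` (Hz) and `psd` (power per Hz, one-sided).
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  nwin <- round(window_s * fs)
  stopifnot(length(x) >= nwin)
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1)) # Hann
  u <- sum(w^2)
  segs <- vapply(starts, function(s) x[s:(s + nwin - 1L)] * w,
                 numeric(nwin))
  spec <- stats::mvfft(segs)
  nf <- floor(nwin / 2) + 1L
  p <- rowMeans(Mod(spec[1:nf, , drop = FALSE])^2) / (fs * u)
  # one-sided: double all bins except DC (and Nyquist when nwin is even)
  scale <- rep(2, nf)
  scale[1] <- 1
  if (nwin %% 2 == 0) scale[nf] <- 1
  list(freq = (0:(nf - 1)) * fs / nwin, psd = p * scale)
}

#' Direct periodogram (oracle spectral estimate)
#'
#' Single untapered periodogram of the whole signal; used as the independent
#' cross-check for Welch band powers.
#'
#' @inheritParams welch_psd
#' @return list with `freq` and `psd` as in [welch_psd()].
#' @export
periodogram_psd <- function(x, fs) {
  n <- length(x)
  spec <- stats::fft(x)
  nf <- floor(n / 2) + 1L
  p <- (Mod(spec[1:nf])^2) / (fs * n)
  scale <- rep(2, nf)
  scale[1] <- 1
  if (n %% 2 == 0) scale[nf] <- 1
  list(freq = (0:(nf - 1)) * fs / n, psd = p * scale)
}

# Mean PSD over [low, high) on the frequency grid (inclusive-low,
# exclusive-high band edges).
band_mean <- function(psd, low, high) {
  sel <- psd$freq >= low & psd$freq < high
  if (!any(sel)) return(0)
  mean(psd$psd[sel])
}
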