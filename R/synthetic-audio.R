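#' Audio clip container
#'
#' Mono waveform in `[-1, 1]` with sample rate and song metadata. The default
#' rate (22.05 kHz) is sufficient for every frame-level feature the pipeline
#' computes while keeping synthetic fixtures small.
#'
#' @param samples numeric vector in `[-1, 1]`.
#' @param sample_rate Hz.
#' @param song_id identifier.
#' @param genre genre label.
#' @param focus_target planted focus value in `[0, 1]` (synthetic clips), or
#'   `NA`.
#' @return object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate = 22050, song_id = NA_character_,
                       genre = NA_character_, focus_target = NA_real_) {
  stopifnot(length(samples) >= 1, sample_rate > 0)
  if (max(abs(samples)) > 1 + 1e-9) stop("samples must lie in [-1, 1]")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 song_id = song_id, genre = genre,
                 focus_target = focus_target),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %s: %.1f s @ %d Hz, genre %s, focus target %s\n",
              x$song_id, length(x$samples) / x$sample_rate, x$sample_rate,
              x$genre, format(x$focus_target)))
  invisible(x)
}

#' Generate a synthetic audio clip with a planted spectral profile
#'
#' Synthesizes a mono clip from spectrally shaped noise plus an optional
#' harmonic tone stack, amplitude-modulated at a tempo-like rate. The
#' `brightness` parameter tilts the noise spectrum (0 = dark/low-passed,
#' 0.5 = white, 1 = bright/high-passed), so it moves the spectral centroid
#' monotonically: synthetic song sets plant `focus_target` as a linear
#' function of brightness, giving the audio model a known recoverable map.
#'
#' @param duration_s clip length in seconds (> 0).
#' @param spectral_params list with any of: `level` (peak amplitude, 0 gives
#'   silence), `brightness` in `[0, 1]`, `tone_freq` (Hz or `NULL`),
#'   `tone_level` relative tone strength, `tempo_bpm` amplitude-modulation
#'   rate (0 = none), `mod_depth` in `[0, 1]`.
#' @param seed integer seed.
#' @param sample_rate Hz (default 22050).
#' @param song_id,genre,focus_target metadata carried on the clip.
#' @return an [audio_clip()].
#' @examples
#' white <- generate_audio(2, list(brightness = 0.5), seed = 1)
#' quiet <- generate_audio(1, list(level = 0))
#' @export
generate_audio <- function(duration_s, spectral_params = list(), seed = NULL,
                           sample_rate = 22050, song_id = NA_character_,
                           genre = NA_character_, focus_target = NA_real_) {
  stopifnot(duration_s > 0)
  p <- utils::modifyList(list(level = 0.9, brightness = 0.5, tone_freq = NULL,
                              tone_level = 0, tempo_bpm = 0, mod_depth = 0.5),
                         spectral_params)
  n <- round(duration_s * sample_rate)
  if (p$level <= 0) {
    return(audio_clip(numeric(n), sample_rate, song_id, genre, focus_target))
  }
  with_seed(seed, {
    x <- stats::rnorm(n)
    # spectral tilt: gain(f) = (f / f_ref)^slope, slope in [-1, 1]
    slope <- 2 * (p$brightness - 0.5)
    if (abs(slope) > 1e-12) {
      X <- stats::fft(x)
      k <- 0:(n - 1)
      k <- pmin(k, n - k)
      f <- k * sample_rate / n
      g <- ifelse(f < 20, 0, (f / 1000)^slope)
      x <- Re(stats::fft(X * g, inverse = TRUE)) / n
    }
    x <- x / max(stats::sd(x), 1e-12)
    if (!is.null(p$tone_freq) && p$tone_level > 0) {
      t <- (seq_len(n) - 1) / sample_rate
      tone <- 0
      for (h in 1:3) {
        tone <- tone + (0.6^(h - 1)) * sin(2 * pi * h * p$tone_freq * t +
                                             stats::runif(1, 0, 2 * pi))
      }
      x <- x + p$tone_level * tone
    }
    if (p$tempo_bpm > 0 && p$mod_depth > 0) {
      t <- (seq_len(n) - 1) / sample_rate
      env <- 1 - p$mod_depth / 2 + (p$mod_depth / 2) *
        sin(2 * pi * p$tempo_bpm / 60 * t)
      x <- x * env
    }
    x <- p$level * x / max(abs(x))
    audio_clip(x, sample_rate, song_id, genre, focus_target)
  })
}

#' Generate a set of synthetic songs with planted focus targets
#'
#' Draws per-song brightness values and plants `focus_target = brightness`,
#' i.e. a linear relation between a spectral property of the audio and the
#' focus level the clip is meant to evoke. Genres partition the brightness
#' range so genre-level mean scores have a known planted ordering.
#'
#' @param n_songs number of songs.
#' @param duration_s per-song duration in seconds.
#' @param genres character vector of genre labels; brightness ranges are
#'   assigned per genre from low to high in the order given.
#' @param tempo_range BPM range for amplitude modulation.
#' @param seed integer seed.
#' @return list of [audio_clip()]s with song ids `song01`, `song02`, ...
#' @export
make_song_set <- function(n_songs = 18, duration_s = 120,
                          genres = c("lofi", "bright"), tempo_range = c(60, 140),
                          seed = NULL) {
  stopifnot(n_songs >= length(genres))
  with_seed(seed, {
    genre <- rep_len(genres, n_songs)
    ng <- length(genres)
    # genre g occupies brightness band [(g-1)/ng, g/ng]
    gi <- match(genre, genres)
    brightness <- (gi - 1) / ng + stats::runif(n_songs) / ng
    tempo <- stats::runif(n_songs, tempo_range[1], tempo_range[2])
    lapply(seq_len(n_songs), function(i) {
      generate_audio(duration_s,
                     list(brightness = brightness[i], tempo_bpm = tempo[i],
                          tone_freq = 110 * 2^(3 * brightness[i]),
                          tone_level = 0.4),
                     seed = child_seed(seed %||% 0, i, 0, 3),
                     song_id = sprintf("song%02d", i), genre = genre[i],
                     focus_target = brightness[i])
    })
  })
}
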