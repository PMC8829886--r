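# Plain-text and WAV I/O for pipeline artifacts.

#' Write / read an EEG recording as headered CSV
#'
#' Columns: `time_s`, `AF7`, `AF8`, `TP9`, `TP10` (uV) and `gyro_x/y/z`
#' (deg/s). Task intervals and the condition label travel in a JSON sidecar
#' (`<path>.meta.json`).
#'
#' @param rec an [eeg_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(rec, path) {
  n <- nrow(rec$data)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$fs, rec$data)
  if (!is.null(rec$gyro)) df <- cbind(df, rec$gyro)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs = rec$fs, condition = rec$condition,
               intervals = rec$intervals)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_eeg_csv
#' @param path CSV path written by [write_eeg_csv()].
#' @export
read_eeg_csv <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(fs = 1 / stats::median(diff(df$time_s)), condition = NA_character_)
  }
  gyro <- if (all(c("gyro_x", "gyro_y", "gyro_z") %in% names(df))) {
    as.matrix(df[, c("gyro_x", "gyro_y", "gyro_z")])
  }
  intervals <- meta$intervals
  if (!is.null(intervals)) intervals <- as.data.frame(intervals)
  eeg_recording(as.matrix(df[, c("AF7", "AF8", "TP9", "TP10")]),
                fs = meta$fs, gyro = gyro, intervals = intervals,
                condition = meta$condition %||% NA_character_)
}

#' Write the cohort self-report ledger as CSV
#'
#' @param cohort a [generate_cohort()] result.
#' @param path output CSV path.
#' @export
write_reports_csv <- function(cohort, path) {
  utils::write.csv(cohort$reports, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix as CSV with a JSON schema sidecar
#'
#' @param x matrix or data frame of features.
#' @param path output CSV path.
#' @param schema schema data frame ([feature_schema()] or
#'   [audio_feature_schema()]).
#' @export
write_feature_csv <- function(x, path, schema) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  jsonlite::write_json(schema, paste0(path, ".schema.json"), digits = NA)
  invisible(path)
}

#' Write / read a mono WAV file (16-bit PCM)
#'
#' Minimal RIFF/WAVE codec for the synthetic clips; samples are clipped to
#' `[-1, 1]` and quantized to 16 bits.
#'
#' @param clip an [audio_clip()].
#' @param path output WAV path.
#' @export
write_wav <- function(clip, path) {
  x <- pmin(1, pmax(-1, clip$samples))
  pcm <- as.integer(round(x * 32767))
  sr <- as.integer(clip$sample_rate)
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little") # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @param path WAV path.
#' @param ... metadata passed to [audio_clip()].
#' @export
read_wav <- function(path, ...) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop("not a RIFF/WAVE file")
  sr <- NULL
  bits <- NULL
  n_ch <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!nzchar(id)) stop("no data chunk found")
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      n_ch <- fmt[2]
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (id == "data") {
      if (bits != 16) stop("only 16-bit PCM supported")
      pcm <- readBin(con, "integer", size / 2, size = 2, endian = "little")
      if (n_ch > 1) pcm <- pcm[seq(1, length(pcm), by = n_ch)]
      return(audio_clip(pmax(-1, pcm / 32767), sample_rate = sr, ...))
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
}

#' Write a cohort manifest as JSON
#'
#' Records the cohort design (participants, schedule, durations, effects,
#' seed) so any artifact can be regenerated from (config, seed).
#'
#' @param cohort a [generate_cohort()] result.
#' @param path output JSON path.
#' @export
write_cohort_manifest <- function(cohort, path) {
  jsonlite::write_json(list(
    participants = cohort$participants,
    schedule = cohort$schedule,
    durations = cohort$durations,
    effect = as.list(cohort$effect),
    artifact_params = cohort$artifact_params,
    seed = cohort$seed
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
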