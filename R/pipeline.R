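#' Default pipeline configuration
#'
#' All fixed analysis constants in one place: 0.5-70 Hz band-pass with a
#' 60 Hz notch, 5 s windows at 200 ms stride (a 5 Hz trace), 2 SD outlier
#' trimming, 1000 permutations thresholded at the 95th percentile, 50 ms /
#' 25 ms audio frames aggregated over 30 s, and a 0.95 PCA variance target.
#' Cohort-scale parameters (`n_participants`, `durations`) default to a
#' small synthetic cohort; set `durations` to the paradigm's 30 min / 3 min /
#' 3 min / 1 min for full-scale runs.
#'
#' @param ... overrides, as name = value pairs.
#' @return named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_participants = 6L,
    effect = c(silence = 0, playlistA = 0.05, playlistB = 0.08,
               soundscape = 0.15),
    report_noise = 0.05,
    durations = list(preferred = 120, arithmetic = 20, creativity = 20,
                     game = 15),
    band = c(0.5, 70), notch_hz = 60,
    window_s = 5, stride_s = 0.2,
    trim_k = 2,
    n_models = 25L, train_frac = 0.8, num_trees = 200L,
    sigma_s = 2, report_threshold = 0.4,
    n_perm = 1000L, alpha = 0.05, perm_level = 0.95,
    frame_s = 0.050, hop_s = 0.025, audio_window_s = 30,
    variance_target = 0.95, n_val_songs = 4L,
    n_songs = 18L, song_duration_s = 120
  )
  utils::modifyList(cfg, list(...))
}

#' Run one pipeline stage
#'
#' Orchestrates the analysis end to end, stage by stage, writing artifacts
#' and a JSON manifest (stage, config, seed) into `out_dir`. Later stages
#' read the in-memory results of earlier ones via the returned `state`
#' object, so a full run is
#' `state <- run_pipeline("simulate", cfg); state <- run_pipeline("decode",
#' cfg, state = state)` and so on; stages fail with a named missing
#' dependency when invoked out of order.
#'
#' @param stage one of `simulate`, `decode`, `stats`, `audiofeat`,
#'   `audiomodel`, `report` (`decode` includes preprocessing and feature
#'   extraction for the cohort's sessions).
#' @param config a [default_config()] list.
#' @param state result of the previous stage (a `pipeline_state`).
#' @param out_dir directory for artifacts, or `NULL` to skip writing.
#' @return updated `pipeline_state` list.
#' @export
run_pipeline <- function(stage = c("simulate", "decode", "stats", "audiofeat",
                                   "audiomodel", "report"),
                         config = default_config(), state = NULL,
                         out_dir = NULL) {
  stage <- match.arg(stage)
  state <- state %||% structure(list(config = config),
                                class = "pipeline_state")
  need <- function(what) {
    if (is.null(state[[what]])) {
      stop(sprintf("stage '%s' requires missing upstream artifact '%s'",
                   stage, what))
    }
  }
  if (stage == "simulate") {
    state$cohort <- generate_cohort(
      config$n_participants, effect = config$effect,
      noise = config$report_noise, seed = config$seed,
      durations = config$durations)
    state$songs <- make_song_set(config$n_songs, config$song_duration_s,
                                 seed = child_seed(config$seed, 0, 0, 9))
  } else if (stage == "decode") {
    need("cohort")
    state$decoded <- decode_cohort(state$cohort,
                                   n_models = config$n_models,
                                   seed = child_seed(config$seed, 0, 0, 10),
                                   num_trees = config$num_trees,
                                   sigma_s = config$sigma_s,
                                   trim_k = config$trim_k)
  } else if (stage == "stats") {
    need("decoded")
    cs <- condition_summary(state$decoded$traces)
    an <- rm_anova(cs)
    ph <- paired_posthoc(cs, alpha = config$alpha)
    prs <- utils::combn(CONDITIONS, 2)
    ts <- lapply(seq_len(ncol(prs)), function(i) {
      ab <- trace_pair_matrices(state$decoded$traces, prs[1, i], prs[2, i])
      res <- ts_permutation_test(ab$A, ab$B, rate = 5,
                                 n_perm = config$n_perm,
                                 alpha = config$alpha,
                                 level = config$perm_level,
                                 seed = child_seed(config$seed, i, 0, 11))
      data.frame(pair = paste(prs[1, i], prs[2, i], sep = "-"),
                 percent = res$percent_significant,
                 segments = format_intervals(res$intervals))
    })
    state$stats <- list(summary = cs, anova = an, posthoc = ph,
                        timeseries = do.call(rbind, ts))
  } else if (stage == "audiofeat") {
    need("songs")
    state$audio_table <- audio_feature_table(state$songs,
                                             config$frame_s, config$hop_s,
                                             config$audio_window_s)
  } else if (stage == "audiomodel") {
    need("audio_table")
    tab <- state$audio_table
    if (!"focus" %in% names(tab)) tab$focus <- tab$focus_target
    state$audio_model <- fit_audio_model(
      tab, variance_target = config$variance_target,
      n_val = config$n_val_songs,
      seed = child_seed(config$seed, 0, 0, 12))
    state$genres <- genre_report(state$songs, state$audio_model)
  } else if (stage == "report") {
    need("stats")
    state$report <- list(
      anova = state$stats$anova,
      posthoc = state$stats$posthoc,
      timeseries = state$stats$timeseries
    )
  }
  if (!is.null(out_dir)) write_stage(stage, state, out_dir)
  state
}

format_intervals <- function(iv) {
  if (!nrow(iv)) return("")
  paste(sprintf("%.1f-%.1f", iv$start_min, iv$end_min), collapse = "; ")
}

# Align a condition pair's traces into participants x samples matrices.
trace_pair_matrices <- function(traces, condA, condB) {
  parts <- sort(unique(traces$participant))
  get <- function(p, cond) {
    traces$focus[traces$participant == p & traces$condition == cond]
  }
  lens <- min(vapply(parts, function(p) {
    min(length(get(p, condA)), length(get(p, condB)))
  }, numeric(1)))
  A <- t(vapply(parts, function(p) get(p, condA)[1:lens], numeric(lens)))
  B <- t(vapply(parts, function(p) get(p, condB)[1:lens], numeric(lens)))
  list(A = A, B = B)
}

write_stage <- function(stage, state, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stage = stage, seed = state$config$seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   config = state$config)
  jsonlite::write_json(manifest,
                       file.path(out_dir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  if (stage == "simulate") {
    write_reports_csv(state$cohort, file.path(out_dir, "self_reports.csv"))
    write_cohort_manifest(state$cohort, file.path(out_dir, "cohort.json"))
  } else if (stage == "decode") {
    utils::write.csv(state$decoded$traces,
                     file.path(out_dir, "focus_traces.csv"),
                     row.names = FALSE)
    utils::write.csv(state$decoded$selection,
                     file.path(out_dir, "model_selection.csv"),
                     row.names = FALSE)
  } else if (stage == "stats") {
    jsonlite::write_json(list(anova = state$stats$anova),
                         file.path(out_dir, "anova.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(state$stats$posthoc, file.path(out_dir, "posthoc.csv"),
                     row.names = FALSE)
    utils::write.csv(state$stats$timeseries,
                     file.path(out_dir, "timeseries_tests.csv"),
                     row.names = FALSE)
  } else if (stage == "audiofeat") {
    write_feature_csv(state$audio_table,
                      file.path(out_dir, "audio_features.csv"),
                      audio_feature_schema())
  } else if (stage == "audiomodel") {
    utils::write.csv(state$genres$songs, file.path(out_dir, "song_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(retained = state$audio_model$fit$retained,
           best_val_r = state$audio_model$fit$best_val_r),
      file.path(out_dir, "audio_model.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}
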