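#' Study conditions
#'
#' The four audio conditions of the paradigm: silence, two pre-recorded focus
#' playlists, and a personalized generative soundscape.
#' @export
CONDITIONS <- c("silence", "playlistA", "playlistB", "soundscape")

# Session task plan. Each session is a 30 min Preferred Task followed by short
# calibration subtasks: arithmetic (3 min), creativity (3 min) and two 1 min
# game levels. The four calibration subtasks are the "ranked" tasks that feed
# the decoder's training ledger; the Preferred Task contributes two
# self-report labels (first/second half) used for evaluation only.
session_plan <- function(durations) {
  tasks <- c("preferred", "arithmetic", "creativity", "game1", "game2")
  lens <- c(durations$preferred, durations$arithmetic, durations$creativity,
            durations$game, durations$game)
  ends <- cumsum(lens)
  data.frame(task = tasks, start_s = c(0, ends[-5]), end_s = ends)
}

RANKED_TASKS <- c("arithmetic", "creativity", "game1", "game2")

#' Generate a synthetic study cohort
#'
#' Builds a cohort of participants, each completing 4 sessions (one per audio
#' condition, orders counterbalanced by a cyclic Latin square). Every session
#' carries a latent focus profile: participant baseline + a planted
#' per-condition offset + session jitter + a slow Ornstein-Uhlenbeck
#' fluctuation, clipped to `[0, 1]`. Self-reports are time-averaged latent
#' focus plus Gaussian observation noise, clipped to `[0, 1]` (six labels per
#' session: two Preferred-Task halves plus four ranked calibration subtasks).
#' EEG is rendered lazily per session by [render_session_eeg()].
#'
#' Defaults are the study conditions: a 0.15 soundscape-vs-silence offset with
#' smaller playlist offsets, self-report noise SD 0.05, and paradigm-scale task
#' durations (30 min Preferred Task; 3/3/1/1 min calibration subtasks).
#'
#' @param n_participants number of participants (>= 2).
#' @param effect named per-condition focus offsets.
#' @param noise self-report observation noise SD.
#' @param seed integer seed.
#' @param durations list with `preferred`, `arithmetic`, `creativity`, `game`
#'   durations in seconds.
#' @param profile_sd,profile_tau fluctuation SD and timescale (s) of the
#'   latent profile.
#' @param baseline_sd SD of per-participant baseline focus around 0.5.
#' @param session_jitter_sd SD of per-session level jitter.
#' @param artifact_params list with `blink_rate` (per min) and `motion_rate`
#'   (episodes per min) passed to the EEG renderer.
#' @param eeg_params extra arguments for [generate_eeg()] (amplitudes,
#'   coupling, noise levels).
#' @return object of class `synthetic_cohort`: `participants`, `schedule`,
#'   `sessions` (latent profiles + intervals), `reports` (self-report ledger),
#'   `clip_log` (warning records for clipped profiles), `params`, `seed`.
#' @examples
#' coh <- generate_cohort(4, seed = 7,
#'   durations = list(preferred = 60, arithmetic = 15, creativity = 15, game = 10))
#' table(coh$schedule$condition)
#' @export
generate_cohort <- function(n_participants,
                            effect = c(silence = 0, playlistA = 0.05,
                                       playlistB = 0.08, soundscape = 0.15),
                            noise = 0.05, seed = NULL,
                            durations = list(preferred = 1800, arithmetic = 180,
                                             creativity = 180, game = 60),
                            profile_sd = 0.1, profile_tau = 60,
                            baseline_sd = 0.08, session_jitter_sd = 0.02,
                            artifact_params = list(blink_rate = 16,
                                                   motion_rate = 1),
                            eeg_params = list()) {
  stopifnot(n_participants >= 2)
  if (!all(CONDITIONS %in% names(effect))) {
    stop("effect must name all four conditions")
  }
  plan <- session_plan(durations)
  session_len <- max(plan$end_s)

  with_seed(seed, {
    participants <- data.frame(
      participant = seq_len(n_participants),
      age = sample(18:65, n_participants, replace = TRUE),
      working = stats::runif(n_participants) < 0.5,
      baseline = clip01(stats::rnorm(n_participants, 0.5, baseline_sd))
    )

    # Cyclic Latin square: condition order rotates with participant index, so
    # every condition appears once per participant and orders are balanced.
    schedule <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
      data.frame(participant = p, session = 1:4,
                 condition = CONDITIONS[((p - 1) + 0:3) %% 4 + 1])
    }))

    sessions <- list()
    reports <- list()
    clip_log <- list()
    for (p in seq_len(n_participants)) {
      for (s in 1:4) {
        cond <- schedule$condition[schedule$participant == p &
                                     schedule$session == s]
        base <- participants$baseline[p] + effect[[cond]] +
          stats::rnorm(1, 0, session_jitter_sd)
        prof <- random_profile(session_len, baseline = base, sd = profile_sd,
                               tau_s = profile_tau,
                               seed = child_seed(seed %||% 0, p, s, 1))
        nc <- attr(prof, "n_clipped")
        if (nc > 0) {
          clip_log[[length(clip_log) + 1L]] <- data.frame(
            participant = p, session = s, n_clipped = nc)
        }
        key <- session_key(p, s)
        sessions[[key]] <- list(participant = p, session = s,
                                condition = cond, profile = prof,
                                intervals = plan)

        # six labels: preferred halves + four ranked calibration subtasks
        labs <- label_spans(plan)
        lat <- vapply(seq_len(nrow(labs)), function(i) {
          sel <- prof$times >= labs$start_s[i] & prof$times < labs$end_s[i]
          mean(prof$values[sel])
        }, numeric(1))
        reports[[length(reports) + 1L]] <- data.frame(
          participant = p, session = s, condition = cond,
          task = labs$task, label_index = seq_len(nrow(labs)),
          focus_latent = lat,
          focus = clip01(lat + stats::rnorm(nrow(labs), 0, noise))
        )
      }
    }

    structure(list(
      participants = participants,
      schedule = schedule,
      sessions = sessions,
      reports = do.call(rbind, reports),
      clip_log = if (length(clip_log)) do.call(rbind, clip_log) else NULL,
      durations = durations,
      effect = effect,
      artifact_params = artifact_params,
      eeg_params = eeg_params,
      seed = seed
    ), class = "synthetic_cohort")
  })
}

session_key <- function(p, s) sprintf("p%03d_s%d", p, s)

# Self-report label spans: Preferred Task split into exact halves, then the
# four ranked subtasks.
label_spans <- function(plan) {
  pref <- plan[plan$task == "preferred", ]
  half <- (pref$start_s + pref$end_s) / 2
  rbind(
    data.frame(task = c("preferred_1", "preferred_2"),
               start_s = c(pref$start_s, half), end_s = c(half, pref$end_s)),
    data.frame(task = RANKED_TASKS,
               start_s = plan$start_s[match(RANKED_TASKS, plan$task)],
               end_s = plan$end_s[match(RANKED_TASKS, plan$task)])
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants x 4 sessions (%d recordings), seed %s\n",
              nrow(x$participants), length(x$sessions),
              format(x$seed %||% NA)))
  invisible(x)
}

#' Render the EEG recording of one cohort session
#'
#' Deterministically synthesizes the full-session EEG (Preferred Task +
#' calibration subtasks) for a participant/session pair from the cohort's
#' latent profile and artifact parameters, using a child seed of the cohort
#' seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param participant,session indices.
#' @return an [eeg_recording()] with task intervals and condition label.
#' @export
render_session_eeg <- function(cohort, participant, session) {
  ses <- cohort$sessions[[session_key(participant, session)]]
  if (is.null(ses)) stop("no such participant/session in cohort")
  args <- c(list(
    duration_s = max(ses$intervals$end_s),
    profile = ses$profile,
    blink_rate = cohort$artifact_params$blink_rate %||% 16,
    motion_rate = cohort$artifact_params$motion_rate %||% 1,
    seed = child_seed(cohort$seed %||% 0, participant, session, 2),
    condition = ses$condition,
    intervals = ses$intervals
  ), cohort$eeg_params)
  do.call(generate_eeg, args)
}
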