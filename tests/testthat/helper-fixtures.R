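# Shared synthetic fixtures, built in code and cached per test run.

.fixtures <- new.env()

# Tiny artifact-free cohort with short tasks: 4 participants x 4 sessions.
tiny_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(
      4, seed = 7,
      durations = list(preferred = 30, arithmetic = 10, creativity = 10,
                       game = 8),
      artifact_params = list(blink_rate = 0, motion_rate = 0),
      profile_tau = 10)
  }
  .fixtures$cohort
}

# A 12 s recording with a varying profile and default artifacts.
tiny_rec <- function(seed = 1, duration = 12, ...) {
  p <- focus_profile(seq(0, duration, length.out = 13),
                     seq(0.2, 0.8, length.out = 13))
  generate_eeg(duration, p, seed = seed, ...)
}

# Ledger with a planted linear map: a latent drive loads (with opposite
# signs) on every channel's alpha and beta power, as the EEG generator's
# coupling does, and focus is linear in the drive.
fake_ledger <- function(P = 10, sessions = 4, noise = 0, seed = 1) {
  sch <- feature_schema()
  set.seed(seed)
  rows <- P * sessions * 4
  X <- matrix(rnorm(rows * 124), rows, 124, dimnames = list(NULL, sch$name))
  drv <- rnorm(rows)
  for (ch in c("AF7", "AF8", "TP9", "TP10")) {
    X[, paste0("pow_", ch, "_alpha")] <- -drv + 0.2 * rnorm(rows)
    X[, paste0("pow_", ch, "_beta")] <- drv + 0.2 * rnorm(rows)
  }
  focus <- clip01(0.5 + 0.15 * drv + rnorm(rows, 0, noise))
  data.frame(participant = rep(seq_len(P), each = sessions * 4),
             session = rep(rep(seq_len(sessions), each = 4), P),
             task = rep(RANKED_TASKS, P * sessions),
             as.data.frame(X), focus = focus, check.names = FALSE)
}
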