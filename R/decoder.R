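#' Decoded focus trace
#'
#' A focus time series at the segmentation rate (5 Hz for 5 s / 200 ms
#' windows), with a record of any smoothing applied.
#'
#' @param values numeric vector of decoded focus values (finite).
#' @param rate samples per second.
#' @param start_s time of the first value (s).
#' @param sigma_s Gaussian smoothing SD already applied, or `NA`.
#' @return object of class `focus_trace`.
#' @export
focus_trace <- function(values, rate = 5, start_s = 0, sigma_s = NA_real_) {
  stopifnot(all(is.finite(values)), rate > 0)
  structure(list(values = as.numeric(values), rate = rate, start_s = start_s,
                 sigma_s = sigma_s), class = "focus_trace")
}

#' @export
print.focus_trace <- function(x, ...) {
  cat(sprintf("<focus_trace> %d points @ %g Hz (%.1f s), sigma = %s s\n",
              length(x$values), x$rate, length(x$values) / x$rate,
              format(x$sigma_s)))
  invisible(x)
}

#' Per-session task-mean features of a cohort
#'
#' Runs the full preprocessing chain on every cohort session: render EEG,
#' band-pass/notch filter, segment at 5 s / 200 ms, gate calibration-task
#' segments on motion, winsorize features at 2 SD per session, and average
#' features over each ranked calibration subtask.
#'
#' @param cohort a [generate_cohort()] result.
#' @param trim_k SD multiple for outlier trimming (2).
#' @param window_s,stride_s segmentation parameters.
#' @return `data.frame(participant, session, condition, task, n_segments)`
#'   plus the 124 feature columns, one row per ranked subtask with at least
#'   one retained segment; tasks with no valid segments are absent (with a
#'   warning).
#' @export
cohort_task_features <- function(cohort, trim_k = 2, window_s = 5,
                                 stride_s = 0.2) {
  rows <- list()
  dropped <- 0L
  for (key in names(cohort$sessions)) {
    ses <- cohort$sessions[[key]]
    rec <- render_session_eeg(cohort, ses$participant, ses$session)
    rec <- filter_recording(rec)
    segs <- segment_recording(rec, window_s, stride_s)
    cal <- segs[segs$task %in% RANKED_TASKS & segs$retained, , drop = FALSE]
    if (!nrow(cal)) next
    fm <- feature_matrix(rec, cal, window_s)
    fm <- trim_outliers(fm, k = trim_k)
    for (task in RANKED_TASKS) {
      sel <- cal$task == task
      if (!any(sel)) {
        dropped <- dropped + 1L
        next
      }
      mu <- colMeans(fm[sel, , drop = FALSE])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(participant = ses$participant, session = ses$session,
                   condition = ses$condition, task = task,
                   n_segments = sum(sel)),
        as.data.frame(t(mu)))
    }
  }
  if (dropped > 0) {
    warning(sprintf("%d ranked tasks had no valid segments and were dropped",
                    dropped))
  }
  do.call(rbind, rows)
}

#' Build the focus-ranked task ledger
#'
#' Joins per-task mean feature vectors with their self-reported focus labels:
#' one row per (participant, session, ranked calibration subtask). On a
#' cohort matching the study's post-exclusion design (51 participants x 4
#' sessions x 4 ranked subtasks) this yields 816 rows.
#'
#' @param task_features output of [cohort_task_features()].
#' @param reports self-report ledger (`cohort$reports`).
#' @return the ledger data frame; rows whose label is missing are dropped
#'   with a warning.
#' @export
build_task_ledger <- function(task_features, reports) {
  key <- c("participant", "session", "task")
  rep_sub <- reports[reports$task %in% RANKED_TASKS,
                     c(key, "focus"), drop = FALSE]
  out <- merge(task_features, rep_sub, by = key, all.x = TRUE, sort = FALSE)
  miss <- !is.finite(out$focus)
  if (any(miss)) {
    warning(sprintf("%d task rows had no self-report label and were dropped",
                    sum(miss)))
    out <- out[!miss, , drop = FALSE]
  }
  out[order(out$participant, out$session, match(out$task, RANKED_TASKS)), ,
      drop = FALSE]
}

ledger_features <- function(ledger) {
  as.matrix(ledger[, feature_schema()$name, drop = FALSE])
}

#' Train an ensemble of random-forest focus regressors
#'
#' Fits `n_models` random-forest regression models, each on a random subset
#' of `round(train_frac * P)` participants' ledger rows. Subsets are redrawn
#' (bounded retries) until every participant is absent from at least one
#' model, so a held-out model exists for everyone.
#'
#' @param ledger a [build_task_ledger()] result.
#' @param n_models number of models.
#' @param train_frac fraction of participants per training subset (0.8).
#' @param seed integer seed.
#' @param num_trees,min_node_size random-forest hyperparameters.
#' @return a `model_bundle`: ranger models, per-model participant subsets,
#'   feature names and parameters.
#' @export
train_ensemble <- function(ledger, n_models = 25, train_frac = 0.8,
                           seed = NULL, num_trees = 200, min_node_size = 5) {
  parts <- sort(unique(ledger$participant))
  P <- length(parts)
  if (P < 5) stop("need at least 5 participants to train the ensemble")
  k <- round(train_frac * P)
  if (k >= P) k <- P - 1L
  with_seed(seed, {
    subsets <- lapply(seq_len(n_models), function(i) sort(sample(parts, k)))
    for (try in 1:100) {
      uncovered <- parts[vapply(parts, function(p) {
        all(vapply(subsets, function(s) p %in% s, logical(1)))
      }, logical(1))]
      if (!length(uncovered)) break
      m <- sample.int(n_models, 1)
      subsets[[m]] <- sort(sample(setdiff(parts, uncovered[1]), k))
    }
    uncovered <- parts[vapply(parts, function(p) {
      all(vapply(subsets, function(s) p %in% s, logical(1)))
    }, logical(1))]
    if (length(uncovered)) {
      stop("could not cover all participants; increase n_models")
    }
    feats <- ledger_features(ledger)
    models <- lapply(seq_len(n_models), function(m) {
      rows <- ledger$participant %in% subsets[[m]]
      ranger::ranger(x = feats[rows, , drop = FALSE], y = ledger$focus[rows],
                     num.trees = num_trees, min.node.size = min_node_size,
                     seed = child_seed(seed %||% 0, m, 0, 4),
                     num.threads = 1)
    })
    structure(list(models = models, subsets = subsets,
                   feature_names = colnames(feats),
                   params = list(n_models = n_models, train_frac = train_frac,
                                 num_trees = num_trees,
                                 min_node_size = min_node_size, seed = seed)),
              class = "model_bundle")
  })
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %d random-forest models, %d participants per subset\n",
              length(x$models), length(x$subsets[[1]])))
  invisible(x)
}

bundle_predict <- function(bundle, model_id, features) {
  features <- features[, bundle$feature_names, drop = FALSE]
  stats::predict(bundle$models[[model_id]],
                 data = as.data.frame(features))$predictions
}

#' Select the calibration-best model for a participant
#'
#' Among models whose training subset excluded the participant, returns the
#' one with the highest Pearson correlation between its predictions and the
#' participant's self-reported focus on the calibration tasks. Ties (and
#' degenerate correlations, treated as -Inf) resolve to the lowest model id.
#'
#' @param bundle a [train_ensemble()] result.
#' @param calib the participant's ledger rows.
#' @param participant participant id.
#' @return list with `model_id` and `calib_r`.
#' @export
select_model <- function(bundle, calib, participant) {
  eligible <- which(!vapply(bundle$subsets, function(s) participant %in% s,
                            logical(1)))
  if (!length(eligible)) {
    stop(sprintf("no model excludes participant %s", participant))
  }
  feats <- ledger_features(calib)
  rs <- vapply(eligible, function(m) {
    pred <- bundle_predict(bundle, m, feats)
    r <- suppressWarnings(stats::cor(pred, calib$focus))
    if (is.finite(r)) r else -Inf
  }, numeric(1))
  best <- eligible[which.max(rs)]
  list(model_id = best, calib_r = rs[which.max(rs)])
}

#' Decode a 5 Hz focus trace from Preferred-Task segments
#'
#' Applies a selected model to the feature matrix of consecutive Preferred
#' Task segments: one prediction per segment, i.e. a trace at 1/stride Hz.
#'
#' @param bundle a [train_ensemble()] result.
#' @param model_id model to apply.
#' @param features segments x 124 feature matrix (schema column names).
#' @param rate trace rate (Hz), the reciprocal of the segmentation stride.
#' @param start_s time of the first segment (s).
#' @return a [focus_trace()].
#' @export
decode_trace <- function(bundle, model_id, features, rate = 5, start_s = 0) {
  if (!all(bundle$feature_names %in% colnames(features))) {
    stop("feature matrix does not match the model's feature schema")
  }
  focus_trace(bundle_predict(bundle, model_id, features), rate = rate,
              start_s = start_s)
}

#' Gaussian-smooth a focus trace
#'
#' Convolves with a normalized discrete Gaussian kernel (radius 4 sigma)
#' using reflective boundary handling, preserving the trace mean up to
#' boundary effects.
#'
#' @param trace a [focus_trace()].
#' @param sigma_s kernel SD in seconds.
#' @return the smoothed [focus_trace()] with `sigma_s` recorded.
#' @export
smooth_trace <- function(trace, sigma_s = 2) {
  stopifnot(inherits(trace, "focus_trace"), sigma_s > 0)
  x <- trace$values
  n <- length(x)
  sig <- sigma_s * trace$rate
  r <- max(1L, ceiling(4 * sig))
  k <- stats::dnorm(-r:r, sd = sig)
  k <- k / sum(k)
  if (n == 1L) return(trace)
  rpad <- min(r, n - 1L)
  pad <- c(x[(rpad + 1):2], x, x[(n - 1):(n - rpad)])
  if (rpad < r) { # short traces: extend by repeating edge values
    pad <- c(rep(pad[1], r - rpad), pad, rep(pad[length(pad)], r - rpad))
  }
  y <- stats::filter(pad, k, method = "convolution", sides = 2)
  out <- trace
  out$values <- as.numeric(y[(r + 1):(r + n)])
  out$sigma_s <- sigma_s
  out
}

#' Evaluate decoded focus against self-report
#'
#' Binarizes self-reports at `report_threshold` (labels are `report >=
#' threshold`), computes ROC/AUC of the prediction scores, accuracy and a
#' confusion matrix at a score threshold (chosen to maximize accuracy when
#' not given), and the Pearson correlation between predictions and reports.
#'
#' @param predictions numeric prediction scores (e.g. per-task mean decoded
#'   focus).
#' @param reports self-reported focus in `[0, 1]`, same length.
#' @param report_threshold label threshold on the reports (0.4).
#' @param score_threshold score threshold for the confusion matrix; `NULL`
#'   picks the accuracy-maximizing threshold.
#' @return list with `auc`, `accuracy`, `confusion`, `pearson`,
#'   `score_threshold`; `auc` is `NA` (with a message) when the labels are
#'   single-class.
#' @export
evaluate_decoder <- function(predictions, reports, report_threshold = 0.4,
                             score_threshold = NULL) {
  stopifnot(length(predictions) == length(reports))
  labels <- reports >= report_threshold
  pearson <- suppressWarnings(stats::cor(predictions, reports))
  if (length(unique(labels)) < 2) {
    message("single-class labels: AUC undefined")
    return(list(auc = NA_real_, accuracy = NA_real_, confusion = NULL,
                pearson = pearson, score_threshold = NA_real_))
  }
  roc <- pROC::roc(response = labels, predictor = predictions,
                   quiet = TRUE, direction = "<", levels = c(FALSE, TRUE))
  auc <- as.numeric(pROC::auc(roc))
  if (is.null(score_threshold)) {
    cand <- sort(unique(predictions))
    cand <- c(cand[1] - 1e-9, (cand[-1] + cand[-length(cand)]) / 2)
    acc <- vapply(cand, function(th) mean((predictions >= th) == labels),
                  numeric(1))
    score_threshold <- cand[which.max(acc)]
  }
  pred_lab <- predictions >= score_threshold
  confusion <- table(predicted = factor(pred_lab, c(FALSE, TRUE)),
                     reported = factor(labels, c(FALSE, TRUE)))
  list(auc = auc, accuracy = mean(pred_lab == labels), confusion = confusion,
       pearson = pearson, score_threshold = score_threshold)
}

#' Decode Preferred-Task focus traces for a whole cohort
#'
#' End-to-end decoding: builds the task ledger, trains the ensemble, selects
#' each participant's calibration-best held-out model, decodes the Preferred
#' Task of every session into a 5 Hz trace and Gaussian-smooths it. A leakage
#' guard asserts that no participant is decoded by a model trained on their
#' own rows.
#'
#' @param cohort a [generate_cohort()] result.
#' @param n_models,seed,num_trees ensemble parameters ([train_ensemble()]).
#' @param sigma_s smoothing SD in seconds.
#' @param trim_k outlier-trimming SD multiple.
#' @return list: `traces` (long data frame: participant, session, condition,
#'   t_s, focus, latent), `selection`, `bundle`, `ledger`, `task_eval`
#'   (per Preferred-Task half: mean decoded vs reported focus).
#' @export
decode_cohort <- function(cohort, n_models = 25, seed = NULL, num_trees = 200,
                          sigma_s = 2, trim_k = 2) {
  tf <- cohort_task_features(cohort, trim_k = trim_k)
  ledger <- build_task_ledger(tf, cohort$reports)
  bundle <- train_ensemble(ledger, n_models = n_models, seed = seed,
                           num_trees = num_trees)
  parts <- sort(unique(ledger$participant))
  sel <- lapply(parts, function(p) {
    s <- select_model(bundle, ledger[ledger$participant == p, , drop = FALSE], p)
    stopifnot(!(p %in% bundle$subsets[[s$model_id]])) # leakage guard
    data.frame(participant = p, model_id = s$model_id, calib_r = s$calib_r)
  })
  selection <- do.call(rbind, sel)

  traces <- list()
  task_eval <- list()
  for (key in names(cohort$sessions)) {
    ses <- cohort$sessions[[key]]
    p <- ses$participant
    mid <- selection$model_id[selection$participant == p]
    rec <- render_session_eeg(cohort, p, ses$session)
    rec <- filter_recording(rec)
    segs <- segment_recording(rec)
    pref <- segs[segs$task == "preferred", , drop = FALSE]
    if (!nrow(pref)) next
    fm <- trim_outliers(feature_matrix(rec, pref), k = trim_k)
    tr <- decode_trace(bundle, mid, fm, rate = 5,
                       start_s = pref$start_s[1])
    tr <- smooth_trace(tr, sigma_s)
    t_s <- pref$start_s + 5 / 2 # window centers
    latent <- profile_at(ses$profile, t_s)
    traces[[key]] <- data.frame(participant = p, session = ses$session,
                                condition = ses$condition, t_s = t_s,
                                focus = tr$values, latent = latent)
    # per-half evaluation rows (the two Preferred-Task self-report labels)
    half <- stats::median(t_s)
    reps <- cohort$reports
    for (h in 1:2) {
      lab <- reps[reps$participant == p & reps$session == ses$session &
                    reps$task == paste0("preferred_", h), "focus"]
      sel_h <- if (h == 1) t_s <= half else t_s > half
      task_eval[[length(task_eval) + 1L]] <- data.frame(
        participant = p, session = ses$session, condition = ses$condition,
        half = h, predicted = mean(tr$values[sel_h]), reported = lab)
    }
  }
  list(traces = do.call(rbind, traces), selection = selection,
       bundle = bundle, ledger = ledger,
       task_eval = do.call(rbind, task_eval))
}
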