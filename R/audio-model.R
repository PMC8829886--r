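#' PCA transform of an audio feature table
#'
#' Standardizes the 136 property columns (correlation-scale PCA, since the
#' properties have heterogeneous units), drops zero-variance columns with a
#' warning, and keeps the smallest number of components whose cumulative
#' explained variance reaches `variance_target`.
#'
#' @param table an [audio_feature_table()] data frame.
#' @param variance_target cumulative explained-variance fraction (0.95).
#' @return object of class `audio_pca`: `center`, `scale`, `rotation`,
#'   `k` retained components, `explained` per-component fractions,
#'   `feature_names`.
#' @export
fit_audio_pca <- function(table, variance_target = 0.95) {
  sch <- audio_feature_schema()
  X <- as.matrix(table[, sch$name, drop = FALSE])
  sds <- col_sds(X)
  keep <- sds > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d zero-variance audio properties before PCA",
                    sum(!keep)))
  }
  X <- X[, keep, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(expl) >= variance_target)[1]
  structure(list(center = pc$center, scale = pc$scale,
                 rotation = pc$rotation, k = k, explained = expl,
                 feature_names = colnames(X)),
            class = "audio_pca")
}

#' Project an audio feature table onto PCA scores
#'
#' @param pca an [fit_audio_pca()] result.
#' @param table feature table with the schema columns.
#' @return rows x `pca$k` score matrix.
#' @export
audio_pca_scores <- function(pca, table) {
  X <- as.matrix(table[, pca$feature_names, drop = FALSE])
  X <- sweep(sweep(X, 2, pca$center), 2, pca$scale, "/")
  (X %*% pca$rotation)[, seq_len(pca$k), drop = FALSE]
}

#' Song-stratified cross-validation folds
#'
#' Assigns whole songs to validation sets so that temporally adjacent
#' windows of one song never straddle the train/validation split. Each fold
#' holds out `n_val` songs; with `n_folds = NULL`, folds are added (sampling
#' biased toward the least-validated songs) until every song has been
#' validated at least `min_coverage` times.
#'
#' @param song_ids character vector, one entry per table row.
#' @param n_val songs held out per fold (4).
#' @param n_folds number of folds, or `NULL` for coverage-driven.
#' @param min_coverage minimum validations per song when `n_folds` is `NULL`.
#' @param seed integer seed.
#' @return list of folds, each `list(train = song ids, val = song ids)`.
#' @export
song_folds <- function(song_ids, n_val = 4, n_folds = NULL, min_coverage = 3,
                       seed = NULL) {
  songs <- unique(song_ids)
  S <- length(songs)
  if (S < n_val + 1) stop("need at least n_val + 1 distinct songs")
  with_seed(seed, {
    count <- stats::setNames(rep(0L, S), songs)
    folds <- list()
    repeat {
      w <- 1 / (1 + count)
      val <- sample(songs, n_val, prob = w)
      folds[[length(folds) + 1L]] <- list(train = setdiff(songs, val),
                                          val = val)
      count[val] <- count[val] + 1L
      if (!is.null(n_folds)) {
        if (length(folds) >= n_folds) break
      } else if (min(count) >= min_coverage) break
      if (length(folds) > 1000) stop("fold construction did not converge")
    }
    if (!is.null(n_folds) && any(count == 0)) {
      # guarantee coverage: swap never-validated songs into existing folds
      for (s in names(count)[count == 0]) {
        i <- which.max(vapply(folds, function(f) max(count[f$val]),
                              numeric(1)))
        out <- folds[[i]]$val[which.max(count[folds[[i]]$val])]
        folds[[i]]$val <- c(setdiff(folds[[i]]$val, out), s)
        folds[[i]]$train <- setdiff(songs, folds[[i]]$val)
        count[s] <- count[s] + 1L
        count[out] <- count[out] - 1L
      }
    }
    folds
  })
}

fit_lm <- function(X, y) {
  stats::lm.fit(cbind(1, X), y)
}

predict_lm <- function(fit, X) {
  as.numeric(cbind(1, X) %*% fit$coefficients)
}

#' Backward-elimination linear model over PCA components
#'
#' Iteratively fits a linear regression of the focus target on the current
#' component set within each training fold, averages the absolute
#' standardized coefficients across folds, eliminates the component with the
#' smallest average weight, and records the mean validation Pearson
#' correlation at every set size. The final model keeps the set that
#' maximized mean validation correlation and is refit on all rows.
#'
#' @param X rows x components score matrix (from [audio_pca_scores()]).
#' @param y focus target per row.
#' @param song_ids song id per row (defines fold membership).
#' @param folds a [song_folds()] result.
#' @param weight `"abs"` ranks components by mean absolute standardized
#'   coefficient across folds (default); `"signed"` uses the absolute value
#'   of the signed mean.
#' @return object of class `audio_focus_model`: `coefficients` (with
#'   intercept), `retained` component indices, `path`
#'   (`data.frame(n_components, val_r, dropped)`), `val_scores` per-row mean
#'   validation predictions, plus the standardization used for ranking.
#' @export
backward_elim_fit <- function(X, y, song_ids, folds,
                              weight = c("abs", "signed")) {
  weight <- match.arg(weight)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(song_ids) == length(y))
  if (ncol(X) < 2) stop("need at least 2 components")
  xsd <- col_sds(X)
  current <- seq_len(ncol(X))
  path <- list()
  best <- list(r = -Inf, set = current)
  val_pred_best <- NULL
  repeat {
    fold_r <- numeric(length(folds))
    wsum <- matrix(0, length(folds), length(current))
    val_pred <- rep(NA_real_, length(y))
    val_n <- rep(0L, length(y))
    singular <- FALSE
    for (i in seq_along(folds)) {
      tr <- song_ids %in% folds[[i]]$train
      va <- song_ids %in% folds[[i]]$val
      fit <- fit_lm(X[tr, current, drop = FALSE], y[tr])
      if (any(is.na(fit$coefficients))) {
        singular <- TRUE
        break
      }
      beta <- fit$coefficients[-1]
      wsum[i, ] <- beta * xsd[current] # standardized weights
      pv <- predict_lm(fit, X[va, current, drop = FALSE])
      fold_r[i] <- suppressWarnings(stats::cor(pv, y[va]))
      val_pred[va] <- ifelse(is.na(val_pred[va]), 0, val_pred[va]) + pv
      val_n[va] <- val_n[va] + 1L
    }
    if (singular) {
      warning(sprintf("singular design with %d components; stopping elimination",
                      length(current)))
      break
    }
    mean_r <- mean(fold_r, na.rm = TRUE)
    rank_w <- if (weight == "abs") colMeans(abs(wsum)) else abs(colMeans(wsum))
    drop_i <- which.min(rank_w)
    path[[length(path) + 1L]] <- data.frame(
      n_components = length(current), val_r = mean_r,
      dropped = if (length(current) > 1) current[drop_i] else NA_integer_)
    if (mean_r > best$r) {
      best <- list(r = mean_r, set = current)
      val_pred_best <- ifelse(val_n > 0, val_pred / pmax(val_n, 1), NA_real_)
    }
    if (length(current) == 1) break
    current <- current[-drop_i]
  }
  final <- fit_lm(X[, best$set, drop = FALSE], y)
  structure(list(coefficients = final$coefficients, retained = best$set,
                 best_val_r = best$r, path = do.call(rbind, path),
                 val_scores = val_pred_best, weight = weight),
            class = "audio_focus_model")
}

#' @export
print.audio_focus_model <- function(x, ...) {
  cat(sprintf("<audio_focus_model> %d components retained (PC %s), mean validation r = %.3f\n",
              length(x$retained), paste(x$retained, collapse = ", "),
              x$best_val_r))
  invisible(x)
}

#' Fit the full audio-to-focus model
#'
#' Convenience wrapper: PCA to the variance target, song-stratified folds,
#' backward elimination, and a bundle that can score new clips.
#'
#' @param table an [audio_feature_table()] with a `focus` column (target per
#'   30 s window).
#' @param variance_target PCA explained-variance target (0.95).
#' @param n_val validation songs per fold (4).
#' @param n_folds number of folds or `NULL` (coverage-driven).
#' @param seed integer seed.
#' @return object of class `audio_model`: `pca`, `fit`
#'   (the [backward_elim_fit()] result), `folds`, `songs`.
#' @export
fit_audio_model <- function(table, variance_target = 0.95, n_val = 4,
                            n_folds = NULL, seed = NULL) {
  stopifnot("focus" %in% names(table))
  pca <- fit_audio_pca(table, variance_target)
  scores <- audio_pca_scores(pca, table)
  folds <- song_folds(table$song_id, n_val = n_val, n_folds = n_folds,
                      seed = seed)
  fit <- backward_elim_fit(scores, table$focus, table$song_id, folds)
  structure(list(pca = pca, fit = fit, folds = folds,
                 songs = unique(table$song_id)),
            class = "audio_model")
}

#' Predict focus from an audio clip
#'
#' Computes the clip's 30 s property windows, projects them through the
#' model's PCA, and applies the linear model: per-window focus dynamics plus
#' a song score defined as the mean over windows.
#'
#' @param model an [fit_audio_model()] result.
#' @param clip an [audio_clip()] of at least 30 s.
#' @return list with `dynamics` (`data.frame(window, start_s, focus)`) and
#'   `score`.
#' @export
predict_audio_focus <- function(model, clip) {
  tab <- aggregate_audio_features(short_time_audio_features(clip))
  if (!nrow(tab)) stop("clip must contain at least one complete 30 s window")
  preds <- predict_table(model, tab)
  list(dynamics = data.frame(window = tab$window, start_s = tab$start_s,
                             focus = preds),
       score = mean(preds))
}

predict_table <- function(model, table) {
  scores <- audio_pca_scores(model$pca, table)
  predict_lm(model$fit,
             scores[, model$fit$retained, drop = FALSE])
}

#' Threshold focus scores into low/high classes
#'
#' @param scores numeric predicted focus scores.
#' @param reference reference focus values (same length).
#' @param threshold class boundary applied to both (default: median of the
#'   reference).
#' @return list with `labels`, `accuracy`, `confusion`, `auc` (`NA` when the
#'   reference is single-class).
#' @export
classify_low_high <- function(scores, reference,
                              threshold = stats::median(reference)) {
  stopifnot(length(scores) == length(reference))
  ref_lab <- reference >= threshold
  labels <- scores >= threshold
  if (length(unique(ref_lab)) < 2) {
    message("single-class reference: AUC undefined")
    return(list(labels = labels, accuracy = NA_real_, confusion = NULL,
                auc = NA_real_))
  }
  roc <- pROC::roc(response = ref_lab, predictor = scores, quiet = TRUE,
                   direction = "<", levels = c(FALSE, TRUE))
  list(labels = labels, accuracy = mean(labels == ref_lab),
       confusion = table(predicted = factor(labels, c(FALSE, TRUE)),
                         reference = factor(ref_lab, c(FALSE, TRUE))),
       auc = as.numeric(pROC::auc(roc)))
}

#' Genre-level focus report
#'
#' Scores every clip with the audio model and summarizes per genre: the mean
#' of song scores and the mean over songs of the within-song window variance,
#' both sorted descending.
#'
#' @param clips list of [audio_clip()]s with genre labels.
#' @param model an [fit_audio_model()] result.
#' @return list with `songs` (per-song score/variance), `mean_score` and
#'   `mean_variance` genre tables (sorted descending).
#' @export
genre_report <- function(clips, model) {
  rows <- lapply(clips, function(cl) {
    pr <- predict_audio_focus(model, cl)
    v <- if (nrow(pr$dynamics) > 1) stats::var(pr$dynamics$focus) else 0
    data.frame(song_id = cl$song_id, genre = cl$genre, score = pr$score,
               variance = v)
  })
  songs <- do.call(rbind, rows)
  ms <- stats::aggregate(score ~ genre, songs, mean)
  mv <- stats::aggregate(variance ~ genre, songs, mean)
  list(songs = songs[order(-songs$score), ],
       mean_score = ms[order(-ms$score), ],
       mean_variance = mv[order(-mv$variance), ])
}
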