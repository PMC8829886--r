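# Synthetic feature tables built directly on the 136-property schema.
fake_audio_table <- function(n_songs = 12, windows = 5, rank = NULL,
                             seed = 1) {
  set.seed(seed)
  sch <- audio_feature_schema()
  n <- n_songs * windows
  if (is.null(rank)) {
    X <- matrix(rnorm(n * 136), n, 136)
  } else {
    L <- matrix(rnorm(n * rank), n, rank)
    W <- matrix(rnorm(rank * 136), rank, 136)
    X <- L %*% W
  }
  colnames(X) <- sch$name
  data.frame(song_id = rep(sprintf("s%02d", seq_len(n_songs)), each = windows),
             genre = "g", focus_target = NA_real_,
             window = rep(seq_len(windows), n_songs),
             start_s = 0, as.data.frame(X), check.names = FALSE)
}

test_that("PCA reaches the variance target with the minimal component count", {
  tab2 <- fake_audio_table(rank = 2, seed = 2)
  pca <- fit_audio_pca(tab2)
  expect_equal(pca$k, 2)
  expect_gte(sum(pca$explained[1:2]), 1 - 1e-9)

  tab <- fake_audio_table(seed = 3)
  pca_full <- fit_audio_pca(tab, variance_target = 0.95)
  expect_gte(sum(pca_full$explained[seq_len(pca_full$k)]), 0.95)
  expect_lt(sum(pca_full$explained[seq_len(pca_full$k - 1)]), 0.95)
  # orthonormal rotation
  G <- crossprod(pca_full$rotation)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-8, ignore_attr = TRUE)
  # zero-variance columns are dropped with a warning
  tabz <- tab
  tabz$zcr_mean <- 1
  expect_warning(fit_audio_pca(tabz), "zero-variance")
})

test_that("PCA reconstruction error matches uncaptured variance", {
  tab <- fake_audio_table(seed = 4)
  pca <- fit_audio_pca(tab, variance_target = 0.6)
  X <- scale(as.matrix(tab[, pca$feature_names]))
  scores <- audio_pca_scores(pca, tab)
  recon <- scores %*% t(pca$rotation[, seq_len(pca$k)])
  err <- sum((X - recon)^2) / sum(X^2)
  expect_equal(err, 1 - sum(pca$explained[seq_len(pca$k)]), tolerance = 1e-8)
})

test_that("song folds never leak songs and cover every song", {
  ids <- rep(sprintf("s%02d", 1:18), each = 4)
  folds <- song_folds(ids, n_val = 4, seed = 5)
  for (f in folds) {
    expect_equal(length(f$train), 14)
    expect_equal(length(f$val), 4)
    expect_length(intersect(f$train, f$val), 0)
  }
  validated <- table(unlist(lapply(folds, `[[`, "val")))
  expect_equal(sort(names(validated)), sort(unique(ids)))
  expect_true(all(validated >= 3))
  expect_error(song_folds(rep("a", 5), n_val = 4), "distinct songs")
  # fixed fold count still covers all songs
  folds6 <- song_folds(ids, n_val = 4, n_folds = 6, seed = 6)
  expect_length(folds6, 6)
  expect_setequal(unlist(lapply(folds6, `[[`, "val")), unique(ids))
})

test_that("backward elimination walks the full path and keeps signal", {
  set.seed(7)
  tab <- fake_audio_table(n_songs = 12, windows = 6, seed = 7)
  X <- audio_pca_scores(fit_audio_pca(tab, variance_target = 0.7), tab)
  y <- X[, 2] + rnorm(nrow(X), 0, 0.05)
  folds <- song_folds(tab$song_id, n_val = 3, seed = 8)
  fit <- backward_elim_fit(X, y, tab$song_id, folds)
  expect_equal(nrow(fit$path), ncol(X)) # one record per set size
  expect_equal(fit$path$n_components, seq(ncol(X), 1))
  expect_true(2 %in% fit$retained)
  # selected set validates at least as well as the full set (within slack)
  full_r <- fit$path$val_r[1]
  expect_gte(fit$best_val_r, full_r - 0.05)
})

test_that("retention of the informative component is reliable", {
  ret <- elimination_retention(n_runs = 5, seed = 9)
  expect_equal(ret$retention_rate, 1)
})

test_that("prediction contract: song score is the mean of window predictions", {
  songs <- make_song_set(6, duration_s = 61, seed = 10)
  tab <- audio_feature_table(songs)
  tab$focus <- tab$focus_target
  model <- fit_audio_model(tab, n_val = 2, seed = 11)
  pr <- predict_audio_focus(model, songs[[1]])
  expect_equal(pr$score, mean(pr$dynamics$focus))
  expect_equal(nrow(pr$dynamics), 2) # 61 s -> 2 complete windows
  # prediction is invariant to row order of the feature table
  shuf <- tab[sample(nrow(tab)), ]
  expect_equal(sort(neurofocus:::predict_table(model, shuf)),
               sort(neurofocus:::predict_table(model, tab)))
  short <- generate_audio(10, list(), seed = 12)
  expect_error(predict_audio_focus(model, short), "30 s")
})

test_that("thresholded classification behaves at the extremes", {
  ref <- c(0.1, 0.2, 0.7, 0.9)
  cls <- classify_low_high(ref, ref, threshold = 0.5)
  expect_equal(cls$accuracy, 1)
  expect_equal(cls$auc, 1)
  all_high <- classify_low_high(c(0.6, 0.7, 0.8, 0.9), ref, threshold = 0)
  expect_true(all(all_high$labels))
  expect_message(classify_low_high(ref, rep(1, 4), threshold = 0.5),
                 "undefined")
})

test_that("genre reports order genres by planted focus and sort output", {
  songs <- make_song_set(8, duration_s = 31, genres = c("low", "high"),
                         seed = 13)
  tab <- audio_feature_table(songs)
  tab$focus <- tab$focus_target
  model <- fit_audio_model(tab, n_val = 2, seed = 14)
  rep <- genre_report(songs, model)
  expect_equal(rep$mean_score$genre, c("high", "low"))
  expect_true(all(diff(rep$songs$score) <= 0))
  expect_true(all(diff(rep$mean_score$score) <= 0))
  # single-window songs have zero within-song variance
  expect_true(all(rep$songs$variance[!is.na(rep$songs$variance)] >= 0))
  one <- genre_report(songs[1], model)
  expect_equal(one$songs$variance, 0)
})
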