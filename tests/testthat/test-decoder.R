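test_that("the task ledger has one row per ranked subtask", {
  coh <- tiny_cohort()
  tf <- cohort_task_features(coh)
  ledger <- build_task_ledger(tf, coh$reports)
  expect_equal(nrow(ledger), 4 * 4 * 4)
  expect_true(all(table(ledger$participant) == 16))
  expect_true(all(ledger$task %in% RANKED_TASKS))
  expect_true(all(is.finite(as.matrix(ledger[, feature_schema()$name]))))
  # a task with no label is dropped with a warning
  reports2 <- coh$reports[-which(coh$reports$task == "arithmetic")[1], ]
  expect_warning(l2 <- build_task_ledger(tf, reports2), "dropped")
  expect_equal(nrow(l2), 63)
})

test_that("ensemble subsets have the right size and cover every participant", {
  ledger <- fake_ledger(P = 10)
  bundle <- train_ensemble(ledger, n_models = 12, seed = 21, num_trees = 50)
  expect_true(all(vapply(bundle$subsets, length, integer(1)) == 8))
  for (p in 1:10) {
    held_out <- any(!vapply(bundle$subsets, function(s) p %in% s, logical(1)))
    expect_true(held_out)
  }
  # same seed reproduces subsets and predictions
  bundle2 <- train_ensemble(ledger, n_models = 12, seed = 21, num_trees = 50)
  expect_identical(bundle$subsets, bundle2$subsets)
  X <- neurofocus:::ledger_features(ledger)
  expect_equal(neurofocus:::bundle_predict(bundle, 1, X),
               neurofocus:::bundle_predict(bundle2, 1, X))
  expect_error(train_ensemble(fake_ledger(P = 4)), "5 participants")
})

test_that("held-out prediction recovers a noise-free planted map", {
  ledger <- fake_ledger(P = 10, sessions = 8, noise = 0, seed = 2)
  bundle <- train_ensemble(ledger, n_models = 12, seed = 3, num_trees = 200)
  rs <- vapply(1:10, function(p) {
    rows <- ledger[ledger$participant == p, ]
    s <- select_model(bundle, rows, p)
    pred <- neurofocus:::bundle_predict(bundle, s$model_id,
                                        neurofocus:::ledger_features(rows))
    cor(pred, rows$focus)
  }, numeric(1))
  expect_gte(median(rs), 0.95)
})

test_that("model selection maximizes calibration correlation with tie-break", {
  ledger <- fake_ledger(P = 6, noise = 0.02, seed = 4)
  bundle <- train_ensemble(ledger, n_models = 8, seed = 5, num_trees = 50)
  p <- 3
  rows <- ledger[ledger$participant == p, ]
  s <- select_model(bundle, rows, p)
  # recompute eligibility and correlations independently
  eligible <- which(!vapply(bundle$subsets, function(ss) p %in% ss,
                            logical(1)))
  rs <- vapply(eligible, function(m) {
    cor(neurofocus:::bundle_predict(bundle, m,
                                    neurofocus:::ledger_features(rows)),
        rows$focus)
  }, numeric(1))
  expect_equal(s$model_id, eligible[which.max(rs)])
  expect_equal(s$calib_r, max(rs))
  # ties resolve to the lowest model id
  dup <- bundle
  dup$models <- dup$models[c(1, 1)]
  dup$subsets <- dup$subsets[c(1, 1)]
  free <- setdiff(1:6, dup$subsets[[1]])[1]
  rows_f <- ledger[ledger$participant == free, ]
  expect_equal(select_model(dup, rows_f, free)$model_id, 1)
  # no eligible model is an explicit failure
  covered <- bundle
  covered$subsets <- lapply(covered$subsets, function(s) union(s, p))
  expect_error(select_model(covered, rows, p), "no model excludes")
})

test_that("decoded traces run at the segmentation rate", {
  ledger <- fake_ledger(P = 6, seed = 6)
  bundle <- train_ensemble(ledger, n_models = 6, seed = 7, num_trees = 50)
  X <- neurofocus:::ledger_features(ledger)[1:37, ]
  tr <- decode_trace(bundle, 1, X)
  expect_s3_class(tr, "focus_trace")
  expect_equal(length(tr$values), 37)
  expect_equal(tr$rate, 5)
  bad <- X[, 1:50]
  expect_error(decode_trace(bundle, 1, bad), "schema")
})

test_that("Gaussian smoothing preserves constants, mass and reduces variance", {
  cst <- focus_trace(rep(0.4, 100))
  expect_equal(smooth_trace(cst, 2)$values, rep(0.4, 100))

  imp <- focus_trace(c(rep(0, 50), 1, rep(0, 49)))
  sm <- smooth_trace(imp, 1)
  expect_equal(sum(sm$values), 1, tolerance = 1e-9)
  expect_equal(which.max(sm$values), 51)

  set.seed(8)
  for (i in 1:5) {
    x <- focus_trace(runif(200))
    expect_lte(var(smooth_trace(x, 2)$values), var(x$values))
  }
})

test_that("decoder evaluation reduces to textbook AUC on small inputs", {
  labels <- c(0.2, 0.3, 0.6, 0.9) # threshold 0.4 -> F F T T
  perfect <- evaluate_decoder(c(0, 0, 1, 1), labels)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$accuracy, 1)
  anti <- evaluate_decoder(c(1, 1, 0, 0), labels)
  expect_equal(anti$auc, 0)
  # hand-checkable 4-point AUC: one discordant pair out of four
  partial <- evaluate_decoder(c(0.1, 0.8, 0.6, 0.9), labels)
  expect_equal(partial$auc, 0.75)
  # label-shuffled predictions: chance level
  set.seed(9)
  scores <- runif(40)
  labs <- rep(c(0.2, 0.8), 20)
  aucs <- vapply(1:200, function(i) {
    evaluate_decoder(sample(scores), labs)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # single-class labels: AUC undefined, reported as such
  expect_message(ev <- evaluate_decoder(runif(5), rep(0.9, 5)), "undefined")
  expect_true(is.na(ev$auc))
})
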