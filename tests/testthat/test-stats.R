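test_that("RM-ANOVA matches a brute-force sums-of-squares oracle", {
  # hand-worked 3x3 table (integer inputs)
  m <- matrix(c(5, 6, 7,
                4, 6, 8,
                5, 5, 8), 3, byrow = TRUE)
  d <- data.frame(participant = rep(1:3, each = 3),
                  condition = rep(c("a", "b", "c"), 3),
                  focus = as.numeric(t(m)))
  res <- rm_anova(d)
  gm <- mean(m)
  ss_cond <- 3 * sum((colMeans(m) - gm)^2)
  ss_part <- 3 * sum((rowMeans(m) - gm)^2)
  ss_err <- sum((m - gm)^2) - ss_cond - ss_part
  F_oracle <- (ss_cond / 2) / (ss_err / 4)
  expect_equal(res$F, F_oracle, tolerance = 1e-12)
  expect_equal(c(res$df1, res$df2), c(2L, 4L))
  expect_equal(res$p, pf(F_oracle, 2, 4, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("RM-ANOVA degrees of freedom follow the crossing and F=0 degenerates", {
  set.seed(1)
  d <- expand.grid(participant = 1:51, condition = CONDITIONS)
  d$focus <- runif(nrow(d))
  res <- rm_anova(d)
  expect_equal(c(res$df1, res$df2), c(3L, 150L))

  d0 <- expand.grid(participant = 1:6, condition = c("a", "b"))
  d0$focus <- rep(runif(6), 2) # identical across conditions
  r0 <- rm_anova(d0)
  expect_equal(r0$F, 0)

  dm <- d[-1, ] # missing cell
  expect_error(rm_anova(dm), "incomplete")
})

test_that("Holm adjustment equals hand-stepped values and dominates Bonferroni", {
  expect_equal(holm_posthoc(0.2)$adjusted, 0.2)
  expect_equal(holm_posthoc(c(0.01, 0.04, 0.03))$adjusted,
               c(0.03, 0.06, 0.06))
  expect_equal(holm_posthoc(rep(1, 4))$adjusted, rep(1, 4))
  set.seed(2)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    holm <- holm_posthoc(p)$adjusted
    bonf <- pmin(1, length(p) * p)
    expect_true(all(holm >= p))
    expect_true(all(holm <= bonf + 1e-15))
    # equal p-values: Holm coincides with Bonferroni
    pe <- rep(p[1], 4)
    expect_equal(holm_posthoc(pe)$adjusted, pmin(1, 4 * pe))
  }
})

test_that("the run-length permutation test behaves at the extremes", {
  set.seed(3)
  A <- matrix(rnorm(8 * 120, 0.5, 0.1), 8)
  res0 <- ts_permutation_test(A, A, rate = 1, n_perm = 100, seed = 4)
  expect_equal(res0$percent_significant, 0)
  expect_equal(nrow(res0$intervals), 0)

  # constant offset 5x the noise SD: nearly everything significant
  B <- matrix(rnorm(8 * 120, 0.5, 0.1), 8)
  A2 <- matrix(rnorm(8 * 120, 1.0, 0.1), 8)
  res1 <- ts_permutation_test(A2, B, rate = 1, n_perm = 200, seed = 5)
  expect_gte(res1$percent_significant, 95)

  expect_error(ts_permutation_test(A, A[, 1:50], rate = 1), "equal")
  expect_error(ts_permutation_test(A[1:3, ], A[1:3, ], rate = 1),
               "5 participants")
})

test_that("observed statistics are invariant to relabeling and sign flips", {
  set.seed(6)
  A <- matrix(rnorm(10 * 100, 0.5, 0.1), 10)
  B <- matrix(rnorm(10 * 100, 0.55, 0.1), 10)
  res <- ts_permutation_test(A, B, rate = 1, n_perm = 200, seed = 7)
  # relabeling participants leaves the observed t/p series unchanged
  perm <- sample(10)
  res_p <- ts_permutation_test(A[perm, ], B[perm, ], rate = 1, n_perm = 200,
                               seed = 7)
  expect_equal(res_p$t, res$t)
  expect_equal(res_p$p, res$p)
  # a global sign flip (swapping conditions) flips t, keeps p and threshold
  res_f <- ts_permutation_test(B, A, rate = 1, n_perm = 200, seed = 7)
  expect_equal(res_f$t, -res$t)
  expect_equal(res_f$p, res$p)
  expect_equal(res_f$run_threshold, res$run_threshold)
  expect_equal(res_f$mask, res$mask)
})

test_that("5 Hz traces are averaged into per-second bins before testing", {
  set.seed(8)
  A5 <- matrix(rnorm(6 * 50 * 5), 6)
  B5 <- matrix(rnorm(6 * 50 * 5), 6)
  res <- ts_permutation_test(A5, B5, rate = 5, n_perm = 50, seed = 9)
  expect_equal(length(res$p), 50)
})

test_that("significance summaries convert masks to percent and minutes", {
  mk <- function(mask) {
    structure(list(mask = mask,
                   intervals = {
                     r <- neurofocus:::runs_of(mask)
                     data.frame(start_min = (r$start - 1) / 60,
                                end_min = r$end / 60)
                   }),
              class = "perm_test_result")
  }
  half <- mk(c(rep(TRUE, 15 * 60), rep(FALSE, 15 * 60)))
  s <- summarize_significance(half)
  expect_equal(s$percent, 50)
  expect_equal(s$intervals$start_min, 0)
  expect_equal(s$intervals$end_min, 15)

  none <- summarize_significance(mk(rep(FALSE, 100)))
  expect_equal(none$percent, 0)
  expect_equal(nrow(none$intervals), 0)

  full <- summarize_significance(mk(rep(TRUE, 30 * 60)))
  expect_equal(full$percent, 100)
  expect_equal(nrow(full$intervals), 1)
  expect_equal(full$intervals$end_min, 30)
})
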