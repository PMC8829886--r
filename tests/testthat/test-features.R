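tone_seg <- function(freq, fs = 256, amp = 10) {
  t <- (0:(5 * fs - 1)) / fs
  amp * sin(2 * pi * freq * t)
}

test_that("the battery has exactly 124 features in five fixed groups", {
  sch <- feature_schema()
  expect_equal(nrow(sch), 124)
  expect_equal(unname(table(sch$group)[c("power", "symmetric_ratio",
                                         "interaction", "correlation",
                                         "time_domain")]),
               c(28, 14, 16, 42, 24), ignore_attr = TRUE)
  set.seed(1)
  seg <- matrix(rnorm(1280 * 4), ncol = 4)
  fv <- extract_features(seg)
  expect_equal(length(fv), 124)
  expect_identical(names(fv), sch$name)
  expect_true(all(is.finite(fv)))
  # determinism
  expect_identical(fv, extract_features(seg))
})

test_that("band powers localize pure tones and match the periodogram oracle", {
  seg <- cbind(tone_seg(10), tone_seg(2), tone_seg(20), tone_seg(40))
  bp <- band_powers(seg)
  expect_equal(length(bp), 28)
  expect_true(all(bp >= 0))
  ch1 <- bp[1:7]
  expect_equal(names(which.max(ch1)), "pow_AF7_alpha")
  expect_equal(names(which.max(bp[8:14])), "pow_AF8_delta")
  expect_equal(names(which.max(bp[15:21])), "pow_TP9_beta")

  # Welch vs direct periodogram integration, aggregated over noise segments
  set.seed(2)
  wp <- pp <- matrix(0, 100, 7)
  for (i in 1:100) {
    x <- rnorm(1280)
    w <- welch_psd(x, 256)
    pg <- periodogram_psd(x, 256)
    for (b in 1:7) {
      wp[i, b] <- neurofocus:::band_mean(w, BANDS$low[b], BANDS$high[b])
      pp[i, b] <- neurofocus:::band_mean(pg, BANDS$low[b], BANDS$high[b])
    }
  }
  expect_true(all(abs(colMeans(wp) / colMeans(pp) - 1) < 0.05))
})

test_that("symmetric ratios are unit for identical channels and linear", {
  x <- tone_seg(10)
  seg <- cbind(x, x, x, x)
  pw <- band_powers(seg)
  r <- symmetric_power_ratios(pw)
  expect_equal(length(r), 14)
  expect_equal(unname(r), rep(1, 14), tolerance = 1e-10)
  # doubling AF7 power doubles all AF7/AF8 ratios
  pw2 <- pw
  pw2[1:7] <- 2 * pw2[1:7]
  r2 <- symmetric_power_ratios(pw2)
  expect_equal(unname(r2[1:7]), 2 * unname(r[1:7]))
  expect_equal(unname(r2[8:14]), unname(r[8:14]))
  # zero denominator: sentinel 0 with a flag
  pw0 <- pw
  pw0[8:14] <- 0
  r0 <- symmetric_power_ratios(pw0)
  expect_equal(unname(r0[1:7]), rep(0, 7))
  expect_true(all(grepl("^ratio_AF7AF8", attr(r0, "flags"))))
})

test_that("spectral interactions follow their defining formulas", {
  pw <- rep(2, 28)
  names(pw) <- feature_schema()$name[1:28]
  ix <- spectral_interactions(pw)
  expect_equal(length(ix), 16)
  expect_equal(unname(ix[1:4]), c(1, 1, 1, 0.5))
  # engagement strictly increasing in beta, alpha and theta fixed
  pw_hi <- pw
  pw_hi[grep("beta", names(pw_hi))] <- 3
  ix_hi <- spectral_interactions(pw_hi)
  eng <- grep("engagement", names(ix))
  expect_true(all(ix_hi[eng] > ix[eng]))
})

test_that("band correlations detect duplicated channels and white-noise nulls", {
  set.seed(3)
  x <- rnorm(1280)
  seg <- cbind(x, x, rnorm(1280), rnorm(1280))
  cc <- pairwise_band_correlations(seg)
  expect_equal(length(cc), 42)
  expect_true(all(cc >= -1 & cc <= 1))
  # duplicated pair AF7-AF8 has correlation 1 in every band
  expect_equal(unname(cc[grep("^corr_AF7_AF8", names(cc))]), rep(1, 7),
               tolerance = 1e-8)
  # independent channels: mean |r| small over 200 segments
  set.seed(4)
  mean_abs <- mean(vapply(1:200, function(i) {
    seg <- matrix(rnorm(1280 * 4), ncol = 4)
    mean(abs(pairwise_band_correlations(seg)))
  }, numeric(1)))
  expect_lte(mean_abs, 0.1)
})

test_that("time-domain features handle constants and Gaussian noise", {
  cst <- matrix(5, 1280, 4)
  td <- time_domain_features(cst)
  expect_equal(length(td), 24)
  expect_equal(unname(td[c("td_AF7_sd", "td_AF7_entropy", "td_AF7_zerocross")]),
               c(0, 0, 0))
  expect_equal(unname(td["td_AF7_mean"]), 5)

  set.seed(5)
  g <- matrix(rnorm(1280 * 4), ncol = 4)
  tg <- time_domain_features(g)
  expect_lt(abs(tg[["td_AF7_skewness"]]), 0.2)
  expect_lt(abs(tg[["td_AF7_kurtosis"]]), 0.4)
  expect_equal(tg[["td_AF8_zerocross"]], zc <- sum(g[-1, 2] * g[-1280, 2] < 0))
  expect_true(tg[["td_TP9_zerocross"]] >= 0)
})

test_that("outlier trimming clips to the 2 SD boundaries", {
  set.seed(6)
  x <- matrix(rnorm(200 * 5), 200, 5)
  x[1, 1] <- mean(x[, 1]) + 3 * sd(x[, 1])
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  tr <- trim_outliers(x, k = 2)
  expect_equal(tr[1, 1], mu[1] + 2 * sds[1], ignore_attr = TRUE)
  for (j in 1:5) {
    expect_lte(max(tr[, j]), mu[j] + 2 * sds[j] + 1e-12)
    expect_gte(min(tr[, j]), mu[j] - 2 * sds[j] - 1e-12)
  }
  # untouched when already within bounds
  y <- matrix(seq(-1, 1, length.out = 40), 20, 2)
  expect_equal(trim_outliers(y, k = 2), y)
  expect_warning(trim_outliers(x[1, , drop = FALSE]), "2 rows")
})

test_that("feature_matrix agrees with per-segment extraction", {
  rec <- filter_recording(tiny_rec(seed = 11, duration = 12))
  segs <- segment_recording(rec)
  fm <- feature_matrix(rec, segs)
  fv <- extract_features(get_segment(rec, segs$start_s[3]))
  # spectral, ratio and time-domain groups are computed identically
  same <- setdiff(feature_schema()$name,
                  feature_schema()$name[feature_schema()$group == "correlation"])
  expect_equal(fm[3, same], fv[same], tolerance = 1e-10)
  # correlation features come from whole-recording band filtering; they agree
  # closely with the per-segment filter apart from window edge leakage
  corr <- feature_schema()$name[feature_schema()$group == "correlation"]
  expect_gt(cor(fm[3, corr], fv[corr]), 0.95)
})
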