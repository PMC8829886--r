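#' Per-participant condition summaries
#'
#' Collapses decoded Preferred-Task traces to one value per participant and
#' condition (the median decoded focus by default).
#'
#' @param traces long trace data frame (`participant`, `condition`, `focus`),
#'   e.g. from [decode_cohort()].
#' @param stat summary function.
#' @return `data.frame(participant, condition, focus)` with a complete
#'   participant x condition crossing when the input has one.
#' @export
condition_summary <- function(traces, stat = stats::median) {
  out <- stats::aggregate(focus ~ participant + condition, data = traces,
                          FUN = stat)
  out[order(out$participant, out$condition), , drop = FALSE]
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject one-way RM-ANOVA on a complete participant x
#' condition table, via `stats::aov` with a participant error stratum.
#' Degrees of freedom are `(c - 1, (c - 1)(n - 1))`; no sphericity
#' correction is applied.
#'
#' @param summary a [condition_summary()]-shaped data frame with columns
#'   `participant`, `condition`, `focus`.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova <- function(summary) {
  tab <- table(summary$participant, summary$condition)
  if (any(tab != 1)) stop("incomplete participant x condition crossing")
  n <- nrow(tab)
  c <- ncol(tab)
  if (c < 2 || n < 3) stop("need >= 2 conditions and >= 3 participants")
  d <- summary
  d$participant <- factor(d$participant)
  d$condition <- factor(d$condition)
  fit <- stats::aov(focus ~ condition + Error(participant), data = d)
  s <- summary(fit)[["Error: Within"]][[1]]
  Fv <- s["condition", "F value"]
  pv <- s["condition", "Pr(>F)"]
  total_ss <- sum((d$focus - mean(d$focus))^2)
  if (s["condition", "Sum Sq"] <= .Machine$double.eps^0.5 * max(total_ss, 1) ||
      !is.finite(Fv)) { # no condition variance: define F = 0
    Fv <- 0
    pv <- 1
  }
  list(F = Fv, df1 = c - 1L, df2 = (c - 1L) * (n - 1L), p = pv)
}

#' Holm-Bonferroni adjustment
#'
#' Step-down Holm adjustment of a vector of p-values, with monotonicity
#' enforcement (adjusted values are non-decreasing in the raw ordering and
#' never below the raw p).
#'
#' @param p raw p-values in `[0, 1]`.
#' @param alpha familywise significance level.
#' @return list with `adjusted` (same order as input) and `reject` decisions
#'   at `alpha`.
#' @export
holm_posthoc <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  adj <- stats::p.adjust(p, method = "holm")
  list(adjusted = adj, reject = adj < alpha)
}

#' Paired post hoc tests between conditions
#'
#' Paired t-tests for every unordered pair of conditions on the per-
#' participant summaries, Holm-corrected.
#'
#' @param summary a [condition_summary()] result (complete crossing).
#' @param alpha familywise level.
#' @return data frame: pair, mean difference, t, df, raw and adjusted p,
#'   rejection decision.
#' @export
paired_posthoc <- function(summary, alpha = 0.05) {
  conds <- sort(unique(summary$condition))
  wide <- stats::reshape(summary, idvar = "participant",
                         timevar = "condition", direction = "wide")
  cols <- paste0("focus.", conds)
  prs <- utils::combn(conds, 2)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    a <- wide[[paste0("focus.", prs[1, i])]]
    b <- wide[[paste0("focus.", prs[2, i])]]
    tt <- stats::t.test(a, b, paired = TRUE)
    data.frame(pair = paste(prs[1, i], prs[2, i], sep = "-"),
               mean_diff = mean(a - b), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  h <- holm_posthoc(out$p, alpha)
  out$p_adj <- h$adjusted
  out$reject <- h$reject
  out
}

# Vectorized per-column paired t-test p-values for a difference matrix
# (participants x time). Returns two-sided p-values.
paired_t_pvals <- function(D) {
  n <- nrow(D)
  mu <- colMeans(D)
  sd <- col_sds(D)
  t <- mu / (sd / sqrt(n))
  p <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
  p[!is.finite(p)] <- 1
  p
}

# Bin a participants x samples trace matrix into 1 s means.
bin_to_seconds <- function(x, rate) {
  T1 <- floor(ncol(x) / rate)
  sapply(seq_len(T1), function(s) {
    rowMeans(x[, ((s - 1) * rate + 1):(s * rate), drop = FALSE])
  })
}

#' Permutation run-length-corrected per-second time-series test
#'
#' Compares two paired sets of focus traces second by second. The 5 Hz traces
#' are averaged within 1 s bins, a paired t-test is applied to each second,
#' and runs of consecutive `p < alpha` seconds are kept only if their length
#' reaches significance against the null distribution of the maximum run
#' length over `n_perm` sign-flip permutations of the within-participant
#' condition differences (the run-length analogue of cluster-based
#' correction; the kept runs are those whose length is at or beyond the 95th
#' percentile of that null distribution, i.e. permutation p <= 1 - level).
#'
#' @param tracesA,tracesB participants x samples matrices (paired by row).
#' @param rate samples per second of the input traces.
#' @param n_perm number of permutations (1000).
#' @param alpha per-second significance level (0.05).
#' @param level percentile of the null maximum-run distribution (0.95).
#' @param null_stat `"max"` keeps familywise control via the maximum run per
#'   permutation; `"all"` pools every null run length instead.
#' @param seed integer seed for the permutations.
#' @return object of class `perm_test_result`: per-second `t`, `p`,
#'   `run_threshold` (samples), logical `mask`, `intervals` (minutes),
#'   `percent_significant`.
#' @export
ts_permutation_test <- function(tracesA, tracesB, rate = 5, n_perm = 1000,
                                alpha = 0.05, level = 0.95,
                                null_stat = c("max", "all"), seed = NULL) {
  null_stat <- match.arg(null_stat)
  tracesA <- as.matrix(tracesA)
  tracesB <- as.matrix(tracesB)
  if (!all(dim(tracesA) == dim(tracesB))) {
    stop("paired trace matrices must have equal dimensions")
  }
  if (nrow(tracesA) < 5) stop("need >= 5 participants")
  A <- bin_to_seconds(tracesA, rate)
  B <- bin_to_seconds(tracesB, rate)
  D <- A - B
  n <- nrow(D)
  mu <- colMeans(D)
  sd <- col_sds(D)
  tstat <- mu / (sd / sqrt(n))
  p <- paired_t_pvals(D)

  max_run <- function(sig) {
    r <- runs_of(sig)
    if (nrow(r)) max(r$length) else 0L
  }
  with_seed(seed, {
    null_runs <- if (null_stat == "max") numeric(n_perm) else list()
    for (i in seq_len(n_perm)) {
      flips <- sample(c(-1, 1), n, replace = TRUE)
      pp <- paired_t_pvals(D * flips)
      if (null_stat == "max") {
        null_runs[i] <- max_run(pp < alpha)
      } else {
        r <- runs_of(pp < alpha)
        null_runs[[i]] <- if (nrow(r)) r$length else 0L
      }
    }
    null_vec <- unlist(null_runs)
    obs <- runs_of(p < alpha)
    # permutation p-value of each observed run length (add-one correction)
    run_p <- vapply(obs$length, function(L) {
      (1 + sum(null_vec >= L)) / (length(null_vec) + 1)
    }, numeric(1))
    keep <- obs[run_p <= 1 - level, , drop = FALSE]
    threshold <- if (length(null_vec)) {
      cand <- 0:(max(null_vec) + 1L)
      cand[which((1 + vapply(cand, function(L) sum(null_vec >= L), numeric(1))) /
                   (length(null_vec) + 1) <= 1 - level)[1]]
    } else 1L
    mask <- rep(FALSE, length(p))
    for (i in seq_len(nrow(keep))) mask[keep$start[i]:keep$end[i]] <- TRUE
    intervals <- if (nrow(keep)) {
      data.frame(start_min = (keep$start - 1) / 60, end_min = keep$end / 60)
    } else {
      data.frame(start_min = numeric(), end_min = numeric())
    }
    structure(list(t = tstat, p = p, run_threshold = threshold, mask = mask,
                   intervals = intervals,
                   percent_significant = 100 * mean(mask),
                   n_perm = n_perm, alpha = alpha, level = level),
              class = "perm_test_result")
  })
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("<perm_test_result> %d s tested, run threshold %d s, %.1f%% significant\n",
              length(x$p), x$run_threshold, x$percent_significant))
  invisible(x)
}

#' Summarize a time-series permutation test
#'
#' @param result a [ts_permutation_test()] result.
#' @return list with `percent` (percentage of tested samples in surviving
#'   runs) and `intervals` (minutes).
#' @export
summarize_significance <- function(result) {
  list(percent = 100 * mean(result$mask), intervals = result$intervals)
}
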