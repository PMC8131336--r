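# Diagnostic-performance statistics: empirical ROC with a dual AUC
# computation (trapezoid over the curve and Mann-Whitney pair counting,
# asserted to agree), DeLong or bootstrap confidence intervals, Youden
# cutoffs, confusion matrices, and the group-comparison tests.

.check_binary <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) == 2L
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || any(is.na(labels))) {
    stop_lsvar("degenerate_roc", "`scores` and `labels` must be aligned with no missing labels")
  }
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    stop_lsvar("degenerate_roc", "`scores` must be finite numbers")
  }
  if (!any(labels) || all(labels)) {
    stop_lsvar("degenerate_roc", "both classes must be present")
  }
  labels
}

#' Empirical ROC curve with dual AUC computation
#'
#' Thresholds are the unique observed score values plus a sentinel above
#' the maximum; positivity is `score >= threshold`, so sensitivity is
#' non-increasing and specificity non-decreasing as the threshold rises.
#' The AUC is computed twice -- by trapezoidal integration of the curve
#' and as the Mann-Whitney pair statistic (ties counted 1/2) -- and the
#' two values are asserted to agree to 1e-12 before either is returned.
#'
#' @param scores per-patient score values (finite).
#' @param labels logical reference-standard labels (`TRUE` = positive);
#'   both classes must be present.
#' @param ci compute a 95% AUC confidence interval (see [auc_ci95()]).
#' @param ci_method `"delong"` (default, deterministic) or `"bootstrap"`.
#' @param boot_reps,seed bootstrap replicates and seed, used only when
#'   `ci_method = "bootstrap"`.
#' @return an object of class `lsvar_roc`: a list with `curve` (data
#'   frame of `threshold`, `sensitivity`, `specificity`), `auc`,
#'   `auc_ci95`, `youden_cutoff`, `youden_j`, `n_pos`, `n_neg`.
#' @examples
#' r <- empirical_roc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
#' r$auc          # 0.75
#' r$youden_cutoff  # 3
#' @export
empirical_roc <- function(scores, labels, ci = TRUE,
                          ci_method = c("delong", "bootstrap"),
                          boot_reps = 2000, seed = NULL) {
  labels <- .check_binary(scores, labels)
  ci_method <- match.arg(ci_method)
  np <- sum(labels)
  nn <- sum(!labels)

  thr <- c(sort(unique(scores)), Inf)
  tp <- vapply(thr, function(t) sum(scores[labels] >= t), numeric(1))
  tn <- vapply(thr, function(t) sum(scores[!labels] < t), numeric(1))
  fp <- nn - tn

  # Trapezoid in count space (exact integer arithmetic until the final
  # division): sum of (delta FP) x mean TP along increasing thresholds.
  k <- length(thr)
  auc_trap <- sum((fp[-k] - fp[-1]) * (tp[-k] + tp[-1]) / 2) / (np * nn)
  # Mann-Whitney pair counting via midranks.
  r <- rank(scores)
  auc_pairs <- (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
  if (abs(auc_trap - auc_pairs) > 1e-12) {
    stop(sprintf(
      "internal error: trapezoidal AUC (%.15f) and pair-counting AUC (%.15f) disagree",
      auc_trap, auc_pairs
    ))
  }

  sens <- tp / np
  spec <- tn / nn
  j <- tp / np + tn / nn - 1
  # ties (including float-level ties between mathematically equal J
  # values) resolve to the smallest threshold, i.e. the most sensitive
  # of the tied cutoffs
  best <- which(j > max(j) - 1e-12)[1]

  roc <- list(
    curve = data.frame(threshold = thr, sensitivity = sens, specificity = spec),
    auc = auc_pairs,
    auc_ci95 = NULL,
    youden_cutoff = thr[best],
    youden_j = j[best],
    n_pos = np,
    n_neg = nn
  )
  class(roc) <- "lsvar_roc"
  if (ci) {
    roc$auc_ci95 <- auc_ci95(scores, labels, method = ci_method,
                             boot_reps = boot_reps, seed = seed)
  }
  roc
}

#' @export
print.lsvar_roc <- function(x, ...) {
  ci <- if (is.null(x$auc_ci95)) "" else
    sprintf(" (95%% CI %.3f-%.3f)", x$auc_ci95[1], x$auc_ci95[2])
  cat(sprintf(
    "ROC: %d positives vs %d negatives | AUC %.3f%s | Youden cutoff %s (J = %.3f)\n",
    x$n_pos, x$n_neg, x$auc, ci, format(x$youden_cutoff), x$youden_j
  ))
  invisible(x)
}

#' @export
as.data.frame.lsvar_roc <- function(x, ...) x$curve

#' 95% confidence interval for the AUC
#'
#' `method = "delong"` uses the DeLong placement-variance estimate with a
#' normal interval, clipped to `[0, 1]` (deterministic).  `method =
#' "bootstrap"` uses a stratified percentile bootstrap (seedable).
#'
#' @inheritParams empirical_roc
#' @param method `"delong"` or `"bootstrap"`.
#' @return numeric `c(low, high)`.
#' @export
auc_ci95 <- function(scores, labels, method = c("delong", "bootstrap"),
                     boot_reps = 2000, seed = NULL) {
  labels <- .check_binary(scores, labels)
  method <- match.arg(method)
  x <- scores[labels]
  y <- scores[!labels]
  if (method == "delong") {
    if (length(x) < 2 || length(y) < 2) {
      stop_lsvar("undefined_variance",
                 "DeLong variance needs at least 2 observations per class")
    }
    psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
    auc <- mean(psi)
    v10 <- rowMeans(psi)
    v01 <- colMeans(psi)
    s2 <- stats::var(v10) / length(x) + stats::var(v01) / length(y)
    z <- stats::qnorm(0.975)
    lo <- max(0, auc - z * sqrt(s2))
    hi <- min(1, auc + z * sqrt(s2))
    c(lo, hi)
  } else {
    pos_idx <- which(labels)
    neg_idx <- which(!labels)
    boot_auc <- with_seed(seed, {
      vapply(seq_len(boot_reps), function(b) {
        bi <- c(sample(pos_idx, replace = TRUE), sample(neg_idx, replace = TRUE))
        s <- scores[bi]
        l <- labels[bi]
        np <- sum(l)
        (sum(rank(s)[l]) - np * (np + 1) / 2) / (np * sum(!l))
      }, numeric(1))
    })
    unname(stats::quantile(boot_auc, c(0.025, 0.975)))
  }
}

#' Youden-optimal cutoff
#'
#' Maximises Youden's index `J = sensitivity + specificity - 1` over the
#' observed thresholds of a ROC curve.  Ties are broken towards the
#' smallest threshold, i.e. the most sensitive of the tied cutoffs.
#'
#' @param roc an `lsvar_roc` from [empirical_roc()], or a numeric score
#'   vector (then `labels` must be given).
#' @param labels reference labels when `roc` is a score vector.
#' @return a list with `cutoff` and `j`.
#' @export
youden_cutoff <- function(roc, labels = NULL) {
  if (!inherits(roc, "lsvar_roc")) {
    roc <- empirical_roc(roc, labels, ci = FALSE)
  }
  list(cutoff = roc$youden_cutoff, j = roc$youden_j)
}

#' Confusion matrix at a fixed cutoff
#'
#' Positivity rule: `score >= cutoff`.
#'
#' @inheritParams empirical_roc
#' @param cutoff finite decision threshold.
#' @return an object of class `lsvar_confusion`: a list of counts `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  labels <- .check_binary(scores, labels)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff)) {
    stop_lsvar("invalid_score", "`cutoff` must be a single finite number")
  }
  pred <- scores >= cutoff
  cm <- list(
    tp = sum(pred & labels), tn = sum(!pred & !labels),
    fp = sum(pred & !labels), fn = sum(!pred & labels)
  )
  class(cm) <- "lsvar_confusion"
  cm
}

#' Build a confusion matrix from counts
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return an `lsvar_confusion` object.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != as.integer(counts))) {
    stop_lsvar("invalid_score", "confusion counts must be non-negative integers")
  }
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "lsvar_confusion")
}

#' @export
print.lsvar_confusion <- function(x, ...) {
  cat(sprintf("TP %d | TN %d | FP %d | FN %d\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Sensitivity and specificity in percent
#'
#' `sensitivity_pct()` returns `100 * tp / (tp + fn)` and
#' `specificity_pct()` returns `100 * tn / (tn + fp)`, at full precision
#' by default.  `rounded = TRUE` applies the reporting convention: round
#' half-up to integer percent.
#'
#' @param cm an `lsvar_confusion` object.
#' @param rounded round half-up to integer percent.
#' @return percentage.
#' @examples
#' cm <- confusion_matrix(tp = 10, tn = 107, fp = 15, fn = 9)
#' sensitivity_pct(cm, rounded = TRUE)  # 53
#' specificity_pct(cm, rounded = TRUE)  # 88
#' @export
sensitivity_pct <- function(cm, rounded = FALSE) {
  stopifnot(inherits(cm, "lsvar_confusion"))
  if (cm$tp + cm$fn == 0) {
    stop_lsvar("undefined_metric", "sensitivity undefined: no positive cases")
  }
  out <- 100 * cm$tp / (cm$tp + cm$fn)
  if (rounded) round_half_up(out) else out
}

#' @rdname sensitivity_pct
#' @export
specificity_pct <- function(cm, rounded = FALSE) {
  stopifnot(inherits(cm, "lsvar_confusion"))
  if (cm$tn + cm$fp == 0) {
    stop_lsvar("undefined_metric", "specificity undefined: no negative cases")
  }
  out <- 100 * cm$tn / (cm$tn + cm$fp)
  if (rounded) round_half_up(out) else out
}

#' Mann-Whitney U test for two independent samples
#'
#' Thin, policy-carrying wrapper around [stats::wilcox.test()]: the exact
#' null distribution is enumerated when the pooled sample size is at most
#' 12 and there are no ties; otherwise the normal approximation with tie
#' and continuity corrections is used.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact force the exact (`TRUE`) or approximate (`FALSE`) branch;
#'   `NULL` (default) applies the size/ties policy above.
#' @return a list with the U statistic (`u`, pairs won by `a` with ties
#'   counted 1/2) and the two-sided p-value (`p`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # 0.1 (exact)
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  if (length(a) == 0 || length(b) == 0 ||
      any(!is.finite(a)) || any(!is.finite(b))) {
    stop_lsvar("invalid_score", "both samples must be non-empty and finite")
  }
  has_ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) {
    exact <- (length(a) + length(b) <= 12) && !has_ties
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                       alternative = "two.sided")
  )
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Wrapper around [stats::fisher.test()], whose two-sided p-value is the
#' probability-mass convention: the sum of hypergeometric probabilities of
#' all tables no more probable than the observed one.  A table with a zero
#' margin carries no information and returns p = 1.
#'
#' @param table 2x2 matrix (or something coercible) of non-negative
#'   integer counts.
#' @return two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2))  # 2/252
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(!is.finite(table)) ||
      any(table < 0) || any(table != as.integer(table))) {
    stop_lsvar("invalid_score", "`table` must be a 2x2 matrix of non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(1)
  }
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' One-way random-effects intraclass correlation, ICC(1)
#'
#' Interrater reliability from a subjects-by-raters table via the one-way
#' ANOVA decomposition: `ICC(1) = (MSB - MSW) / (MSB + (k - 1) MSW)`,
#' where MSB/MSW are the between- and within-subject mean squares and `k`
#' the number of raters.  The qualitative band follows the conventional
#' 0.4 / 0.6 / 0.75 cuts: below 0.4 poor, 0.4--0.59 fair, 0.6--0.74 good,
#' 0.75--1.0 excellent.
#'
#' @param ratings numeric matrix (or data frame), subjects in rows and
#'   raters in columns; at least 2 of each, no missing cells.
#' @return a list with `icc`, `band`, `msb`, `msw`, `n_subjects`,
#'   `k_raters`.
#' @examples
#' icc_oneway(cbind(c(1, 2, 3), c(1, 2, 3)))$icc  # 1
#' @export
icc_oneway <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (!is.numeric(ratings) || nrow(ratings) < 2 || ncol(ratings) < 2 ||
      any(!is.finite(ratings))) {
    stop_lsvar(
      "invalid_score",
      "`ratings` must be a complete numeric matrix with >= 2 subjects and >= 2 raters"
    )
  }
  n <- nrow(ratings)
  k <- ncol(ratings)
  grand <- mean(ratings)
  subj_means <- rowMeans(ratings)
  ssb <- k * sum((subj_means - grand)^2)
  ssw <- sum((ratings - subj_means)^2)
  if (ssb + ssw == 0) {
    stop_lsvar("undefined_icc", "zero total variance: ICC undefined")
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  band <- if (icc < 0.4) "poor" else if (icc < 0.6) "fair" else
    if (icc < 0.75) "good" else "excellent"
  list(icc = icc, band = band, msb = msb, msw = msw,
       n_subjects = n, k_raters = k)
}
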