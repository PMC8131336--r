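test_that("empirical ROC handles the canonical small cases", {
  r <- empirical_roc(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE), ci = FALSE)
  expect_equal(r$auc, 1.0)
  expect_equal(r$youden_cutoff, 2)
  expect_equal(r$youden_j, 1.0)

  r2 <- empirical_roc(rep(5, 8), rep(c(TRUE, FALSE), 4), ci = FALSE)
  expect_equal(r2$auc, 0.5)
  expect_equal(r2$youden_j, 0.0)

  r3 <- empirical_roc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE), ci = FALSE)
  expect_equal(r3$auc, 0.75)  # 3 concordant of 4 pairs
  expect_equal(r3$youden_cutoff, 3)  # J = 0.5 at cutoffs 3 and 5; tie -> smallest
  expect_equal(r3$youden_j, 0.5)

  expect_error(empirical_roc(1:4, rep(TRUE, 4)), class = "lsvar_degenerate_roc")
  expect_error(empirical_roc(c(1, NA, 3), c(TRUE, FALSE, TRUE)),
               class = "lsvar_degenerate_roc")
})

test_that("ROC curve is monotone and AUC matches brute force and pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(314)
  for (i in 1:40) {
    inst <- random_roc_instance()
    r <- empirical_roc(inst$scores, inst$labels, ci = FALSE)
    expect_true(all(diff(r$curve$sensitivity) <= 1e-12))
    expect_true(all(diff(r$curve$specificity) >= -1e-12))
    expect_equal(r$auc, oracle_auc(inst$scores, inst$labels), tolerance = 1e-12)
    proc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = inst$labels, predictor = inst$scores,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
    )))
    expect_equal(r$auc, proc_auc, tolerance = 1e-10)
  }
})

test_that("AUC is antisymmetric under label swap and invariant to monotone transforms", {
  set.seed(2718)
  for (i in 1:20) {
    inst <- random_roc_instance()
    a1 <- empirical_roc(inst$scores, inst$labels, ci = FALSE)
    a2 <- empirical_roc(inst$scores, !inst$labels, ci = FALSE)
    expect_equal(a1$auc + a2$auc, 1, tolerance = 1e-12)
    f <- function(x) exp(0.7 * x) + x  # strictly increasing
    at <- empirical_roc(f(inst$scores), inst$labels, ci = FALSE)
    expect_equal(at$auc, a1$auc, tolerance = 1e-12)
    expect_equal(at$youden_j, a1$youden_j, tolerance = 1e-12)
  }
})

test_that("DeLong intervals match pROC and respect clipping and symmetry", {
  skip_if_not_installed("pROC")
  set.seed(1618)
  for (i in 1:15) {
    n <- sample(12:60, 1)
    labels <- c(TRUE, TRUE, FALSE, FALSE,
                sample(c(TRUE, FALSE), n - 4, replace = TRUE))
    scores <- stats::rnorm(n, mean = ifelse(labels, 0.7, 0))
    ci <- auc_ci95(scores, labels)
    proc_ci <- as.numeric(pROC::ci.auc(pROC::roc(
      response = labels, predictor = scores,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
    ), method = "delong"))
    expect_equal(ci[1], max(0, proc_ci[1]), tolerance = 1e-8)
    expect_equal(ci[2], min(1, proc_ci[3]), tolerance = 1e-8)
    auc <- empirical_roc(scores, labels, ci = FALSE)$auc
    expect_true(ci[1] <= auc && auc <= ci[2])
  }

  # perfect separation, large n: upper bound clipped to 1
  scores <- c(stats::rnorm(50, 10), stats::rnorm(50, -10))
  labels <- rep(c(TRUE, FALSE), each = 50)
  expect_equal(auc_ci95(scores, labels)[2], 1)

  # symmetric data around AUC 0.5: interval symmetric about 0.5
  s <- c(1, 2, 3, 4)
  l <- c(TRUE, FALSE, FALSE, TRUE)
  ci <- auc_ci95(s, l)
  expect_equal(ci[1] + ci[2], 1, tolerance = 1e-9)

  # n = 2 per class: finite, ordered interval
  ci2 <- auc_ci95(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(is.finite(ci2)) && ci2[1] <= ci2[2])
  expect_error(auc_ci95(c(1, 2, 3), c(TRUE, FALSE, FALSE)),
               class = "lsvar_undefined_variance")
})

test_that("bootstrap CI is seeded and brackets the AUC", {
  set.seed(11)
  scores <- stats::rnorm(60, mean = rep(c(1, 0), 30))
  labels <- rep(c(TRUE, FALSE), 30)
  ci1 <- auc_ci95(scores, labels, method = "bootstrap", boot_reps = 300, seed = 5)
  ci2 <- auc_ci95(scores, labels, method = "bootstrap", boot_reps = 300, seed = 5)
  expect_identical(ci1, ci2)
  auc <- empirical_roc(scores, labels, ci = FALSE)$auc
  expect_true(ci1[1] <= auc && auc <= ci1[2])
})

test_that("Youden cutoff equals the exhaustive confusion-matrix scan", {
  set.seed(99)
  for (i in 1:40) {
    inst <- random_roc_instance()
    got <- youden_cutoff(inst$scores, inst$labels)
    want <- oracle_youden(inst$scores, inst$labels)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$j, want$j, tolerance = 1e-12)
  }
})

test_that("confusion matrices count the positivity rule score >= cutoff", {
  cm <- confusion_at_cutoff(c(0.8, 0.22), c(TRUE, FALSE), 0.67)
  expect_equal(unclass(cm), list(tp = 1L, tn = 1L, fp = 0L, fn = 0L),
               ignore_attr = TRUE)
  scores <- c(1, 2, 3, 4)
  labels <- c(FALSE, TRUE, FALSE, TRUE)
  low <- confusion_at_cutoff(scores, labels, 0)   # everything positive
  expect_equal(low$fn + low$tn, 0)
  high <- confusion_at_cutoff(scores, labels, 99) # nothing positive
  expect_equal(high$tp + high$fp, 0)
  cm2 <- confusion_at_cutoff(scores, labels, 2.5)
  expect_equal(cm2$tp + cm2$tn + cm2$fp + cm2$fn, length(scores))
})

test_that("sensitivity/specificity reproduce the reported integer percentages", {
  cm <- confusion_matrix(tp = 10, tn = 107, fp = 15, fn = 9)
  expect_equal(sensitivity_pct(cm), 100 * 10 / 19)
  expect_equal(sensitivity_pct(cm, rounded = TRUE), 53)
  expect_equal(specificity_pct(cm, rounded = TRUE), 88)
  cm2 <- confusion_matrix(tp = 18, tn = 109, fp = 13, fn = 1)
  expect_equal(sensitivity_pct(cm2, rounded = TRUE), 95)
  expect_equal(specificity_pct(cm2, rounded = TRUE), 89)
  cm3 <- confusion_matrix(1, 1, 0, 0)
  expect_equal(sensitivity_pct(cm3), 100)
  expect_equal(specificity_pct(cm3), 100)
  expect_error(sensitivity_pct(confusion_matrix(0, 5, 2, 0)),
               class = "lsvar_undefined_metric")
  expect_error(specificity_pct(confusion_matrix(3, 0, 0, 1)),
               class = "lsvar_undefined_metric")
  expect_error(confusion_matrix(-1, 0, 0, 0), class = "lsvar_invalid_score")
})

test_that("Mann-Whitney branches: exact enumeration, ties, and agreement at n = 6 + 6", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1.0)
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1)  # 2 of the C(6,3) = 20 rank splits are as extreme
  expect_equal(res$u, 0)
  big <- mann_whitney_u(stats::rnorm(40, 0), stats::rnorm(40, 5))
  expect_lt(big$p, 0.001)
  expect_error(mann_whitney_u(numeric(), 1:3), class = "lsvar_invalid_score")

  set.seed(12)
  for (i in 1:20) {
    a <- stats::rnorm(6)
    b <- stats::rnorm(6, 0.5)
    p_exact <- mann_whitney_u(a, b, exact = TRUE)$p
    p_approx <- mann_whitney_u(a, b, exact = FALSE)$p
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2)), 1.0)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2)), 1.0)  # zero margin
  expect_equal(fisher_exact(matrix(c(2, 7, 0, 0), 2)), 1.0)
  expect_error(fisher_exact(matrix(c(1.5, 0, 0, 1), 2)),
               class = "lsvar_invalid_score")

  # all 2x2 tables with N <= 12, plus random tables up to N = 20
  for (n in 2:12) {
    for (r1 in 0:n) {
      for (c1 in 0:n) {
        for (a in max(0, r1 + c1 - n):min(r1, c1)) {
          tab <- matrix(c(a, c1 - a, r1 - a, n - r1 - c1 + a), 2)
          expect_equal(fisher_exact(tab), oracle_fisher(tab), tolerance = 1e-9)
        }
      }
    }
  }
  set.seed(8)
  for (i in 1:50) {
    tab <- matrix(stats::rmultinom(1, sample(13:20, 1), rep(0.25, 4)), 2)
    expect_equal(fisher_exact(tab), oracle_fisher(tab), tolerance = 1e-9)
  }
})

test_that("one-way ICC matches closed forms, ANOVA, and the interpretation bands", {
  # identical raters, distinct subjects: MSW = 0 -> ICC 1
  expect_equal(icc_oneway(cbind(1:5, 1:5, 1:5))$icc, 1.0)
  # crossed pair: MSB = 0, k = 2 -> ICC -1
  expect_equal(icc_oneway(rbind(c(1, 2), c(2, 1)))$icc, -1.0)
  expect_error(icc_oneway(matrix(3, 4, 2)), class = "lsvar_undefined_icc")
  expect_error(icc_oneway(matrix(1:4, 1)), class = "lsvar_invalid_score")

  # cross-check MSB/MSW against a one-way ANOVA fit
  set.seed(4)
  ratings <- matrix(stats::rnorm(30, rep(stats::rnorm(10, sd = 2), 3)), 10, 3)
  res <- icc_oneway(ratings)
  long <- data.frame(
    y = as.vector(ratings),
    subject = factor(rep(seq_len(nrow(ratings)), ncol(ratings)))
  )
  tab <- summary(stats::aov(y ~ subject, data = long))[[1]]
  expect_equal(res$msb, tab["subject", "Mean Sq"], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(res$msw, tab["Residuals", "Mean Sq"], tolerance = 1e-10,
               ignore_attr = TRUE)

  # interpretation bands at the conventional 0.4 / 0.6 / 0.75 cuts:
  # a 2-rater table with subject variance 1 and noise variance
  # (1 - icc)/icc has population ICC(1) = icc.
  mk <- function(icc) {
    n <- 400
    set.seed(1)
    subj <- stats::rnorm(n, sd = 1)
    noise_sd <- sqrt((1 - icc) / icc)
    cbind(subj + stats::rnorm(n, sd = noise_sd),
          subj + stats::rnorm(n, sd = noise_sd))
  }
  expect_equal(icc_oneway(mk(0.92))$band, "excellent")
  expect_equal(icc_oneway(mk(0.65))$band, "good")
  expect_equal(icc_oneway(mk(0.5))$band, "fair")
  expect_equal(icc_oneway(mk(0.1))$band, "poor")
})
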