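# Independent brute-force oracles used to cross-check the package's
# diagnostics implementations.  These deliberately share no code with the
# implementation: the AUC oracle loops over all positive-negative pairs,
# the Youden oracle scans candidate cutoffs through confusion counts, and
# the Fisher oracle enumerates the hypergeometric support directly.

# O(n^2) pair-counting AUC: P(score_pos > score_neg) + 0.5 P(equal).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (x in pos) {
    for (y in neg) {
      total <- total + (x > y) + 0.5 * (x == y)
    }
  }
  total / (length(pos) * length(neg))
}

# Exhaustive Youden scan over candidate cutoffs (unique scores plus a
# sentinel), positivity score >= cutoff, ties -> smallest cutoff.
oracle_youden <- function(scores, labels) {
  cand <- c(sort(unique(scores)), Inf)
  best_j <- -Inf
  best_c <- NA_real_
  for (ct in cand) {
    sens <- mean(scores[labels] >= ct)
    spec <- mean(scores[!labels] < ct)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_c <- ct
    }
  }
  list(cutoff = best_c, j = best_j)
}

# Two-sided Fisher p by direct enumeration of the hypergeometric support
# (probability-mass convention, 1e-7 relative slack on the inclusion rule).
oracle_fisher <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random ROC instance with ties (scores snapped to a coarse grid).
random_roc_instance <- function(n_max = 50) {
  n <- sample(4:n_max, 1)
  labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
  scores <- round(stats::rnorm(n, mean = ifelse(labels, 0.5, 0), sd = 1), 1)
  list(scores = scores, labels = labels)
}

# Minimal two-patient cohort mirroring a cirrhotic / normal example pair.
two_patient_cohort <- function() {
  data.frame(
    id = c("pos", "neg"),
    stiffness_kpa = c(6.7, 2.2),
    vol_I_III_ml = c(400, 220),
    vol_IV_VIII_ml = c(2000, 1000),
    splenic_volume_ml = c(500, 200),
    vein1_hu = c(NA, 145), vein2_hu = c(NA, 145), vein3_hu = c(NA, 145),
    ivc_hu = c(115, 110),
    veins_contrasted = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}
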