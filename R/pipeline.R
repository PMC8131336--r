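# Study orchestration: cohort CSV I/O, the end-to-end analysis run
# (scores -> descriptive comparisons -> ROC/Youden/confusion blocks ->
# optional reliability), and report serialization.

.mandatory_cols <- c("id", "stiffness_kpa", "vol_I_III_ml", "vol_IV_VIII_ml",
                     "vein1_hu", "ivc_hu", "veins_contrasted")
.known_cols <- c(.mandatory_cols, "splenic_volume_ml", "vein2_hu", "vein3_hu")

#' Read / write a cohort CSV
#'
#' The schema is one row per patient with unit-suffixed columns: `id`,
#' `stiffness_kpa`, `vol_I_III_ml`, `vol_IV_VIII_ml`, optional
#' `splenic_volume_ml`, `vein1_hu` (`vein2_hu`, `vein3_hu` optional),
#' `ivc_hu`, `veins_contrasted` (logical).  Unknown columns are preserved
#' as pass-through covariates.  Malformed rows are rejected with their row
#' numbers; a missing mandatory column raises a schema error listing the
#' missing names.
#'
#' @param path CSV file path.
#' @return `read_cohort_csv()` returns the validated cohort data frame;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    stop_lsvar("schema_error", sprintf("cohort file not found: %s", path))
  }
  cohort <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) {
      stop_lsvar("schema_error",
                 sprintf("could not parse %s as a cohort CSV: %s",
                         path, conditionMessage(e)))
    }
  )
  if (nrow(cohort) == 0) {
    stop_lsvar("schema_error", sprintf("%s contains no patient rows", path))
  }
  missing <- setdiff(.mandatory_cols, names(cohort))
  if (length(missing) > 0) {
    stop_lsvar("schema_error",
               sprintf("missing mandatory column(s): %s",
                       paste(missing, collapse = ", ")))
  }
  cohort$veins_contrasted <- as.logical(cohort$veins_contrasted)
  validate_cohort(cohort)
}

#' Validate a cohort data frame against the schema
#'
#' @param cohort data frame to validate.
#' @return the cohort, invisibly unchanged, when valid.
#' @keywords internal
#' @export
validate_cohort <- function(cohort) {
  missing <- setdiff(.mandatory_cols, names(cohort))
  if (length(missing) > 0) {
    stop_lsvar("schema_error",
               sprintf("missing mandatory column(s): %s",
                       paste(missing, collapse = ", ")))
  }
  bad_row <- function(cond) which(cond)
  problems <- character()
  num_bad <- function(x, positive = TRUE) {
    !is.na(x) & (!is.finite(x) | (positive & x <= 0))
  }
  checks <- list(
    "non-positive or non-finite stiffness_kpa" =
      is.na(cohort$stiffness_kpa) | num_bad(cohort$stiffness_kpa),
    "non-positive or non-finite vol_I_III_ml" =
      is.na(cohort$vol_I_III_ml) | num_bad(cohort$vol_I_III_ml),
    "non-positive or non-finite vol_IV_VIII_ml" =
      is.na(cohort$vol_IV_VIII_ml) | num_bad(cohort$vol_IV_VIII_ml),
    "non-positive splenic_volume_ml" =
      if ("splenic_volume_ml" %in% names(cohort))
        num_bad(cohort$splenic_volume_ml) else logical(nrow(cohort)),
    "NA veins_contrasted" = is.na(cohort$veins_contrasted),
    "veins_contrasted but no vein HU" =
      !is.na(cohort$veins_contrasted) & cohort$veins_contrasted &
        Reduce(`&`, lapply(intersect(c("vein1_hu", "vein2_hu", "vein3_hu"),
                                     names(cohort)),
                           function(cl) is.na(cohort[[cl]])))
  )
  for (what in names(checks)) {
    rows <- bad_row(checks[[what]])
    if (length(rows) > 0) {
      problems <- c(problems,
                    sprintf("%s in row(s) %s", what,
                            paste(rows, collapse = ", ")))
    }
  }
  if (length(problems) > 0) {
    stop_lsvar("schema_error", paste(problems, collapse = "; "))
  }
  invisible(cohort)
}

#' @rdname read_cohort_csv
#' @param cohort cohort data frame to write.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

.score_column <- function(scored, score_var) {
  switch(score_var,
    lsvr = scored$lsvr,
    lsvar = scored$lsvar,
    lvca = as.numeric(scored$lvca),
    splenic_volume = scored$splenic_volume_ml,
    stop_lsvar("config_error", sprintf("unknown score '%s'", score_var))
  )
}

#' Run the full study analysis
#'
#' Scores every patient, splits the cohort at the stiffness threshold,
#' and produces the descriptive block (per-group medians/IQRs with
#' Mann-Whitney p-values; Fisher's exact test for logical covariates),
#' the diagnostic block (per-score ROC with AUC + 95% CI, the
#' Youden-optimal cutoff and confusion/sensitivity/specificity at the
#' Youden cutoff and at any configured fixed cutoffs) and, when a ratings
#' table is supplied, the reliability block (one-way ICC per score).
#' Patients without a splenic volume are excluded from the splenic-volume
#' evaluation only, never from the score evaluations.
#'
#' @param input one of: a cohort data frame, a path to a cohort CSV, a
#'   [cohort_config] (a synthetic cohort is generated), or a list of
#'   [labeled_volume] phantoms whose `meta` carries `id` and
#'   `stiffness_kpa` (they are measured with [measure_patient()]).
#' @param threshold_kpa stiffness threshold defining the positive group
#'   (default 3.5 kPa; positivity is `stiffness >= threshold`).
#' @param score_vars scores to evaluate.
#' @param fixed_cutoffs named list of extra cutoffs to tabulate per
#'   score, in addition to the Youden cutoff.
#' @param ci_method AUC confidence-interval method, see [auc_ci95()].
#' @param ratings optional named list of subjects-by-raters matrices (one
#'   per score) for the reliability block.
#' @param seed seed recorded in provenance and used for synthetic input
#'   and bootstrap CIs.
#' @param tolerance_hu isoattenuation band half-width for LVCA scoring.
#' @param verbose emit messages describing the applied settings.
#' @return an object of class `lsvar_report` with elements `descriptive`,
#'   `diagnostic`, `reliability`, `provenance`.
#' @examples
#' rep <- run_study(cohort_config(seed = 1), seed = 1)
#' rep$diagnostic$lsvar$auc
#' @export
run_study <- function(input, threshold_kpa = 3.5,
                      score_vars = c("lsvr", "lsvar", "lvca", "splenic_volume"),
                      fixed_cutoffs = list(lsvr = 0.34, lsvar = c(0.67, 0.47)),
                      ci_method = c("delong", "bootstrap"),
                      ratings = NULL, seed = NULL, tolerance_hu = 20,
                      verbose = FALSE) {
  ci_method <- match.arg(ci_method)
  if (threshold_kpa <= 0 || !is.finite(threshold_kpa)) {
    stop_lsvar("config_error", "`threshold_kpa` must be positive and finite")
  }
  if (length(fixed_cutoffs) && any(!is.finite(unlist(fixed_cutoffs)))) {
    stop_lsvar("config_error", "fixed cutoffs must be finite")
  }
  input_mode <- NULL
  config_echo <- NULL
  if (inherits(input, "cohort_config")) {
    input_mode <- "synthetic"
    if (!is.null(seed) && is.null(input$seed)) input$seed <- seed
    config_echo <- unclass(input)
    config_echo$strata <- as.list(config_echo$strata)
    cohort <- generate_cohort(input)
  } else if (is.character(input)) {
    input_mode <- "csv"
    cohort <- read_cohort_csv(input)
  } else if (is.data.frame(input)) {
    input_mode <- "data.frame"
    cohort <- validate_cohort(input)
  } else if (is.list(input) && all(vapply(input, inherits, logical(1),
                                          "labeled_volume"))) {
    input_mode <- "phantoms"
    cohort <- do.call(rbind, lapply(input, function(ph) {
      m <- measure_patient(ph)
      data.frame(
        id = ph$meta$id %||% "<unknown>",
        stiffness_kpa = ph$meta$stiffness_kpa %||% NA_real_,
        vol_I_III_ml = m$volumes$vol_I_III_ml,
        vol_IV_VIII_ml = m$volumes$vol_IV_VIII_ml,
        splenic_volume_ml = m$volumes$splenic_volume_ml,
        vein1_hu = m$attenuation$vein_hu,
        ivc_hu = m$attenuation$ivc_hu,
        veins_contrasted = m$attenuation$veins_contrasted,
        stringsAsFactors = FALSE
      )
    }))
    if (any(is.na(cohort$stiffness_kpa))) {
      stop_lsvar("schema_error",
                 "phantom metadata must carry stiffness_kpa for every patient")
    }
    validate_cohort(cohort)
  } else {
    stop_lsvar("schema_error",
               "`input` must be a cohort data frame, CSV path, cohort_config or phantom list")
  }

  if (verbose) {
    message(sprintf(
      "settings: threshold %.2f kPa (positive = stiffness >= threshold), LVCA isoattenuation band +/- %g HU, positivity score >= cutoff, Youden ties -> smallest cutoff, AUC CI method %s",
      threshold_kpa, tolerance_hu, ci_method
    ))
  }

  scored <- score_cohort(cohort, tolerance_hu = tolerance_hu)
  positive <- scored$stiffness_kpa >= threshold_kpa
  if (!any(positive) || all(positive)) {
    stop_lsvar("degenerate_study",
               sprintf("cohort has a single class at threshold %.2f kPa", threshold_kpa))
  }

  # ---- descriptive block (per-group median [IQR] + group test) --------
  desc_vars <- c(
    lvca = "lvca", lsvr = "lsvr", lsvar = "lsvar",
    vol_I_III_ml = "vol_I_III_ml", vol_IV_VIII_ml = "vol_IV_VIII_ml",
    total_volume_ml = NA, splenic_volume_ml = "splenic_volume_ml"
  )
  scored$total_volume_ml <- scored$vol_I_III_ml + scored$vol_IV_VIII_ml
  descriptive <- lapply(names(desc_vars), function(nm) {
    x <- scored[[nm]]
    if (is.null(x)) return(NULL)
    neg <- x[!positive & !is.na(x)]
    pos <- x[positive & !is.na(x)]
    q <- function(v) unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
    qn <- q(neg)
    qp <- q(pos)
    list(
      variable = nm,
      negative = list(n = length(neg), median = qn[2], q25 = qn[1], q75 = qn[3]),
      positive = list(n = length(pos), median = qp[2], q25 = qp[1], q75 = qp[3]),
      p_mann_whitney = mann_whitney_u(neg, pos)$p
    )
  })
  names(descriptive) <- names(desc_vars)
  descriptive <- Filter(Negate(is.null), descriptive)
  # Fisher's exact test for any logical covariates present
  logical_covs <- setdiff(
    names(scored)[vapply(scored, is.logical, logical(1))],
    "veins_contrasted"
  )
  for (cv in logical_covs) {
    x <- scored[[cv]]
    ok <- !is.na(x)
    tab <- table(factor(x[ok], c(FALSE, TRUE)), factor(positive[ok], c(FALSE, TRUE)))
    descriptive[[cv]] <- list(
      variable = cv,
      negative = list(n = sum(ok & !positive),
                      count = sum(x[ok & !positive])),
      positive = list(n = sum(ok & positive),
                      count = sum(x[ok & positive])),
      p_fisher = fisher_exact(tab)
    )
  }

  # ---- diagnostic block ------------------------------------------------
  diagnostic <- lapply(score_vars, function(sv) {
    x <- .score_column(scored, sv)
    keep <- !is.na(x)
    x <- x[keep]
    lab <- positive[keep]
    # the DeLong variance needs 2 observations per class; tiny studies
    # still get the point estimates
    want_ci <- sum(lab) >= 2 && sum(!lab) >= 2
    roc <- empirical_roc(x, lab, ci = want_ci, ci_method = ci_method,
                         seed = seed)
    cutoffs <- unique(c(roc$youden_cutoff, fixed_cutoffs[[sv]]))
    at <- lapply(cutoffs, function(ct) {
      cm <- confusion_at_cutoff(x, lab, ct)
      list(
        cutoff = ct,
        is_youden = identical(ct, roc$youden_cutoff),
        confusion = unclass(cm),
        sensitivity_pct = sensitivity_pct(cm),
        specificity_pct = specificity_pct(cm),
        sensitivity_pct_rounded = sensitivity_pct(cm, rounded = TRUE),
        specificity_pct_rounded = specificity_pct(cm, rounded = TRUE)
      )
    })
    list(
      score = sv, n = length(x), n_pos = sum(lab), n_neg = sum(!lab),
      auc = roc$auc, auc_ci95 = roc$auc_ci95,
      youden_cutoff = roc$youden_cutoff, youden_j = roc$youden_j,
      at_cutoffs = at,
      curve = roc$curve
    )
  })
  names(diagnostic) <- score_vars

  # ---- reliability block ----------------------------------------------
  reliability <- NULL
  if (!is.null(ratings)) {
    reliability <- lapply(ratings, function(r) {
      res <- icc_oneway(r)
      res[c("icc", "band", "n_subjects", "k_raters")]
    })
  }

  report <- list(
    descriptive = descriptive,
    diagnostic = diagnostic,
    reliability = reliability,
    provenance = list(
      input_mode = input_mode,
      n = nrow(scored),
      n_positive = sum(positive),
      n_negative = sum(!positive),
      threshold_kpa = threshold_kpa,
      tolerance_hu = tolerance_hu,
      positivity_rule = "score >= cutoff",
      youden_tie_rule = "smallest cutoff",
      ci_method = ci_method,
      seed = seed,
      config = config_echo,
      package_version = as.character(utils::packageVersion("lsvar")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  class(report) <- "lsvar_report"
  report
}

#' @export
print.lsvar_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("Study report: n = %d (%d positive / %d negative at >= %.2f kPa)\n\n",
              p$n, p$n_positive, p$n_negative, p$threshold_kpa))
  cat("Descriptive (median [IQR], group comparison p):\n")
  for (d in x$descriptive) {
    if (!is.null(d$p_mann_whitney)) {
      cat(sprintf("  %-18s neg %7.2f [%7.2f-%7.2f] (n=%3d) | pos %7.2f [%7.2f-%7.2f] (n=%2d) | p = %s\n",
                  d$variable,
                  d$negative$median, d$negative$q25, d$negative$q75, d$negative$n,
                  d$positive$median, d$positive$q25, d$positive$q75, d$positive$n,
                  format.pval(d$p_mann_whitney, digits = 3, eps = 0.001)))
    } else {
      cat(sprintf("  %-18s neg %d/%d | pos %d/%d | Fisher p = %s\n",
                  d$variable, d$negative$count, d$negative$n,
                  d$positive$count, d$positive$n,
                  format.pval(d$p_fisher, digits = 3, eps = 0.001)))
    }
  }
  cat("\nDiagnostic performance:\n")
  for (d in x$diagnostic) {
    ci_txt <- if (is.null(d$auc_ci95)) "" else
      sprintf(" (95%% CI %.2f-%.2f)", d$auc_ci95[1], d$auc_ci95[2])
    cat(sprintf("  %-15s AUC %.2f%s, Youden cutoff %.2f (J = %.2f), n = %d\n",
                d$score, d$auc, ci_txt, d$youden_cutoff, d$youden_j, d$n))
    for (a in d$at_cutoffs) {
      cat(sprintf("    cutoff %.2f%s: TP %d TN %d FP %d FN %d | sens %d%% spec %d%%\n",
                  a$cutoff, if (a$is_youden) " (Youden)" else "",
                  a$confusion$tp, a$confusion$tn, a$confusion$fp, a$confusion$fn,
                  a$sensitivity_pct_rounded, a$specificity_pct_rounded))
    }
  }
  if (!is.null(x$reliability)) {
    cat("\nInterrater reliability (one-way ICC):\n")
    for (nm in names(x$reliability)) {
      r <- x$reliability[[nm]]
      cat(sprintf("  %-15s ICC = %.2f (%s; %d subjects x %d raters)\n",
                  nm, r$icc, r$band, r$n_subjects, r$k_raters))
    }
  }
  invisible(x)
}

#' Serialize a study report
#'
#' Writes `report.json` (full precision), `report.txt` (the printed
#' tables, ratios to 2 decimals and percentages as integers) and one
#' `roc_<score>.csv` per evaluated score into `dir`.
#'
#' @param report an `lsvar_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "lsvar_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- unclass(report)
  json$diagnostic <- lapply(json$diagnostic, function(d) {
    d$curve <- NULL  # curves go to the CSV exports
    d
  })
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(utils::capture.output(print(report)), file.path(dir, "report.txt"))
  for (nm in names(report$diagnostic)) {
    utils::write.csv(report$diagnostic[[nm]]$curve,
                     file.path(dir, sprintf("roc_%s.csv", nm)),
                     row.names = FALSE)
  }
  invisible(dir)
}
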