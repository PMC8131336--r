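#' Classify the liver vein to cava attenuation (LVCA) score
#'
#' The LVCA is an ordinal four-category score read from a portal venous CT
#' scan: the mean attenuation of the hepatic veins (measured 1 cm proximal
#' to the vein confluence) is compared with the attenuation of the inferior
#' vena cava (1 cm below the confluence).
#'
#' Categories:
#' \describe{
#'   \item{1}{hyperattenuating -- veins more than `tolerance_hu` HU denser
#'     than the IVC}
#'   \item{2}{isoattenuating -- mean vein density within `tolerance_hu` HU
#'     of the IVC (the boundary is inclusive)}
#'   \item{3}{hypoattenuating -- veins more than `tolerance_hu` HU less
#'     dense than the IVC}
#'   \item{4}{veins not contrasted at all (a visual call, supplied as the
#'     `veins_contrasted` flag; no HU rule applies)}
#' }
#'
#' Up to three hepatic veins are averaged with equal weights.  Anatomy
#' varies, so one or two measurable veins are accepted, with a warning.
#'
#' @param vein_hu numeric vector of 1--3 mean hepatic-vein densities (HU).
#'   `NA` entries mark veins that could not be measured.  Ignored when
#'   `veins_contrasted` is `FALSE`.
#' @param ivc_hu mean density of the inferior vena cava (HU).
#' @param veins_contrasted logical; `FALSE` means the liver veins show no
#'   visible contrast, which forces score 4.
#' @param tolerance_hu half-width of the isoattenuation band (HU, > 0).
#'   Default 20.
#' @return integer LVCA score in `1:4`.
#' @examples
#' classify_lvca(c(140, 140, 140), 100)   # hyperattenuating -> 1
#' classify_lvca(c(70, 70, 70), 100)      # hypoattenuating  -> 3
#' classify_lvca(numeric(), NA, veins_contrasted = FALSE)  # -> 4
#' @seealso [compute_lsvar()] which multiplies the LVCA into the LSVR.
#' @export
classify_lvca <- function(vein_hu, ivc_hu, veins_contrasted = TRUE,
                          tolerance_hu = 20) {
  if (!is.numeric(tolerance_hu) || length(tolerance_hu) != 1 ||
      !is.finite(tolerance_hu) || tolerance_hu <= 0) {
    stop_lsvar("invalid_measurement", "`tolerance_hu` must be a single positive number")
  }
  if (!is.logical(veins_contrasted) || length(veins_contrasted) != 1 ||
      is.na(veins_contrasted)) {
    stop_lsvar("invalid_measurement", "`veins_contrasted` must be TRUE or FALSE")
  }
  if (!veins_contrasted) {
    return(4L)
  }
  vein_hu <- vein_hu[!is.na(vein_hu)]
  if (length(vein_hu) == 0) {
    stop_lsvar(
      "invalid_measurement",
      "veins_contrasted is TRUE but no hepatic-vein HU value was supplied"
    )
  }
  if (length(vein_hu) > 3) {
    stop_lsvar("invalid_measurement", "at most 3 hepatic-vein HU values are expected")
  }
  check_finite_hu(vein_hu, "hepatic-vein attenuation")
  if (length(ivc_hu) != 1 || is.na(ivc_hu)) {
    stop_lsvar("invalid_measurement", "`ivc_hu` must be a single HU value")
  }
  check_finite_hu(ivc_hu, "IVC attenuation")
  if (length(vein_hu) < 3) {
    warn_lsvar(
      "vein_subset",
      sprintf("only %d of 3 hepatic veins measured; averaging the available veins",
              length(vein_hu))
    )
  }
  d <- mean(vein_hu) - ivc_hu
  if (abs(d) <= tolerance_hu) {
    2L
  } else if (d > tolerance_hu) {
    1L
  } else {
    3L
  }
}

#' Compute the liver segmental volume ratio (LSVR)
#'
#' The LSVR is the volume of Couinaud segments I--III divided by the volume
#' of segments IV--VIII.  Cirrhotic remodeling (hypertrophy of the left and
#' caudate lobes, atrophy of the right lobe) drives the ratio up.
#'
#' @param vol_I_III volume of Couinaud segments I--III (ml, > 0).
#' @param vol_IV_VIII volume of Couinaud segments IV--VIII (ml, > 0).
#' @return the dimensionless ratio, at full floating precision (rounding to
#'   the 2 decimals used in reports happens only at the reporting layer).
#'   Vectorised over both arguments.
#' @examples
#' compute_lsvr(400, 2000)   # 0.2
#' compute_lsvr(333, 1237)   # 0.269..., prints as 0.27
#' @export
compute_lsvr <- function(vol_I_III, vol_IV_VIII) {
  if (!is.numeric(vol_I_III) || !is.numeric(vol_IV_VIII)) {
    stop_lsvar("invalid_volume", "volumes must be numeric (ml)")
  }
  if (any(!is.finite(vol_I_III)) || any(!is.finite(vol_IV_VIII)) ||
      any(vol_I_III <= 0) || any(vol_IV_VIII <= 0)) {
    stop_lsvar("invalid_volume", "segmental volumes must be finite and > 0 ml")
  }
  vol_I_III / vol_IV_VIII
}

#' Compute the liver segmental volume and attenuation ratio (LSVAR)
#'
#' The composite score is the product of the volume ratio and the ordinal
#' attenuation score: `LSVAR = LSVR * LVCA`.
#'
#' @param lsvr liver segmental volume ratio (> 0), e.g. from
#'   [compute_lsvr()].
#' @param lvca LVCA score, integer-valued in `1:4`, e.g. from
#'   [classify_lvca()].
#' @return the composite ratio.  Vectorised over both arguments.
#' @examples
#' compute_lsvar(0.2, 4)    # 0.8
#' compute_lsvar(0.22, 1)   # 0.22
#' @export
compute_lsvar <- function(lsvr, lvca) {
  if (!is.numeric(lsvr) || any(!is.finite(lsvr)) || any(lsvr <= 0)) {
    stop_lsvar("invalid_score", "`lsvr` must be finite and > 0")
  }
  if (!is.numeric(lvca) || any(is.na(lvca)) || any(lvca != as.integer(lvca)) ||
      any(!(lvca %in% 1:4))) {
    stop_lsvar("invalid_score", "`lvca` must be an ordinal score in {1, 2, 3, 4}")
  }
  lsvr * as.numeric(lvca)
}

#' Derive the score panel for one patient record
#'
#' Composes [classify_lvca()], [compute_lsvr()] and [compute_lsvar()] on a
#' single patient's measurements and passes the splenic volume through.
#'
#' @param record a list or single-row data frame with fields
#'   `vol_I_III_ml`, `vol_IV_VIII_ml`, `ivc_hu`, `veins_contrasted`, either
#'   a `vein_hu` vector or columns `vein1_hu`/`vein2_hu`/`vein3_hu`, and
#'   optionally `splenic_volume_ml` and `id`.
#' @param tolerance_hu passed to [classify_lvca()].
#' @return an object of class `lsvar_panel`: a list with elements `lvca`,
#'   `lsvr`, `lsvar` and `splenic_volume_ml` (`NA` when absent).
#' @examples
#' score_patient(list(
#'   id = "fig3-cirrhotic", vol_I_III_ml = 400, vol_IV_VIII_ml = 2000,
#'   vein_hu = c(60, 60, 60), ivc_hu = 120, veins_contrasted = FALSE
#' ))
#' @export
score_patient <- function(record, tolerance_hu = 20) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1) {
      stop_lsvar("invalid_measurement", "`record` must describe exactly one patient")
    }
    record <- as.list(record)
  }
  id <- record$id %||% "<unknown>"
  vein_hu <- record$vein_hu %||%
    unlist(record[intersect(c("vein1_hu", "vein2_hu", "vein3_hu"), names(record))],
           use.names = FALSE)
  rescope <- function(expr) {
    tryCatch(expr, lsvar_error = function(e) {
      stop_lsvar(
        sub("^lsvar_", "", class(e)[[1]]),
        sprintf("patient %s: %s", id, conditionMessage(e))
      )
    })
  }
  lvca <- rescope(classify_lvca(
    vein_hu, record$ivc_hu,
    veins_contrasted = as.logical(record$veins_contrasted %||% TRUE),
    tolerance_hu = tolerance_hu
  ))
  lsvr <- rescope(compute_lsvr(record$vol_I_III_ml, record$vol_IV_VIII_ml))
  panel <- list(
    lvca = lvca,
    lsvr = lsvr,
    lsvar = compute_lsvar(lsvr, lvca),
    splenic_volume_ml = as.numeric(record$splenic_volume_ml %||% NA_real_)
  )
  class(panel) <- "lsvar_panel"
  panel
}

#' @export
print.lsvar_panel <- function(x, ...) {
  cat(sprintf(
    "LVCA %d | LSVR %.2f | LSVAR %.2f | splenic volume %s ml\n",
    x$lvca, x$lsvr, x$lsvar,
    ifelse(is.na(x$splenic_volume_ml), "--",
           format(round(x$splenic_volume_ml)))
  ))
  invisible(x)
}

#' Score every patient in a cohort table
#'
#' Applies [score_patient()] row-wise and appends `lvca`, `lsvr` and
#' `lsvar` columns.  Warnings about patients measured with fewer than three
#' hepatic veins are collapsed into a single summary warning.
#'
#' @param cohort a cohort data frame (see [read_cohort_csv()] for the
#'   column schema; [generate_cohort()] produces one).
#' @param tolerance_hu passed to [classify_lvca()].
#' @return `cohort` with the three score columns appended.
#' @export
score_cohort <- function(cohort, tolerance_hu = 20) {
  if (!is.data.frame(cohort)) {
    stop_lsvar("schema_error", "`cohort` must be a data frame")
  }
  n_subset <- 0L
  panels <- lapply(seq_len(nrow(cohort)), function(i) {
    withCallingHandlers(
      score_patient(cohort[i, , drop = FALSE], tolerance_hu = tolerance_hu),
      lsvar_vein_subset = function(w) {
        n_subset <<- n_subset + 1L
        invokeRestart("muffleWarning")
      }
    )
  })
  if (n_subset > 0) {
    warn_lsvar(
      "vein_subset",
      sprintf("%d patient(s) measured with fewer than 3 hepatic veins; available veins averaged",
              n_subset)
    )
  }
  cohort$lvca <- vapply(panels, `[[`, integer(1), "lvca")
  cohort$lsvr <- vapply(panels, `[[`, numeric(1), "lsvr")
  cohort$lsvar <- vapply(panels, `[[`, numeric(1), "lsvar")
  cohort
}
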