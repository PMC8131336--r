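# Labeled CT-like voxel phantoms: representation, measurement, generation,
# and NIfTI I/O.  The phantom stands in for a segmented portal venous CT:
# volumetry is voxel counting over a segment-label map and attenuation is
# the mean HU over a labeled ROI.

#' Region label code table
#'
#' Fixed, versioned code table for the label map of a [labeled_volume]:
#' `1:8` are Couinaud segments I--VIII, `10` the spleen, `20` the hepatic
#' veins, `21` the inferior vena cava and `0` background.
#'
#' @return named integer vector mapping region names to label codes.
#' @examples
#' label_codes()[["spleen"]]
#' @export
label_codes <- function() {
  c(
    background = 0L,
    segment_I = 1L, segment_II = 2L, segment_III = 3L,
    segment_IV = 4L, segment_V = 5L, segment_VI = 6L,
    segment_VII = 7L, segment_VIII = 8L,
    spleen = 10L,
    hepatic_veins = 20L,
    ivc = 21L
  )
}

.resolve_code <- function(code) {
  tab <- label_codes()
  if (is.character(code)) {
    if (!code %in% names(tab)) {
      stop_lsvar("invalid_volume", sprintf("unknown region name '%s'", code))
    }
    return(unname(tab[[code]]))
  }
  code <- as.integer(code)
  if (length(code) != 1 || is.na(code) || !code %in% tab) {
    stop_lsvar("invalid_volume", sprintf("unknown region code %s", format(code)))
  }
  code
}

#' Construct a labeled voxel volume
#'
#' @param hu 3D numeric array of attenuations (HU).
#' @param labels 3D integer array of region codes (same shape as `hu`;
#'   codes from [label_codes()]).
#' @param spacing voxel edge lengths in mm along the three axes.
#' @param meta optional list of provenance metadata (seed, patient id,
#'   stiffness, ...), carried through I/O.
#' @return an object of class `labeled_volume`.
#' @export
labeled_volume <- function(hu, labels, spacing = c(1, 1, 1), meta = list()) {
  if (!is.array(hu) || length(dim(hu)) != 3) {
    stop_lsvar("invalid_volume", "`hu` must be a 3D array")
  }
  if (!is.array(labels) || !identical(dim(labels), dim(hu))) {
    stop_lsvar("invalid_volume", "`labels` must be a 3D array with the same shape as `hu`")
  }
  if (!is.numeric(spacing) || length(spacing) != 3 || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop_lsvar("invalid_volume", "`spacing` must be 3 positive voxel edge lengths (mm)")
  }
  known <- unname(label_codes())
  present <- unique(as.vector(labels))
  if (any(!present %in% known)) {
    stop_lsvar(
      "invalid_volume",
      sprintf("label map contains undeclared codes: %s",
              paste(setdiff(present, known), collapse = ", "))
    )
  }
  structure(
    list(hu = hu, labels = labels, spacing = as.numeric(spacing), meta = meta),
    class = "labeled_volume"
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf(
    "labeled_volume: %s voxels @ %s mm, %d labeled regions\n",
    paste(dim(x$hu), collapse = "x"),
    paste(format(x$spacing, trim = TRUE), collapse = "x"),
    length(setdiff(unique(as.vector(x$labels)), 0L))
  ))
  invisible(x)
}

#' Volume of a labeled region in ml
#'
#' Voxel-counting volumetry: the number of voxels carrying the region code
#' times the voxel volume (product of the spacings, mm^3), reported in ml.
#' An absent label yields 0 ml.
#'
#' @param v a [labeled_volume].
#' @param code region code or region name (see [label_codes()]).
#' @return volume in ml.
#' @examples
#' codes <- label_codes()
#' lab <- array(0L, c(10, 10, 10)); lab[1:10, 1:10, 1:5] <- codes[["spleen"]]
#' v <- labeled_volume(array(100, c(10, 10, 10)), lab, spacing = c(1, 1, 1))
#' region_volume_ml(v, "spleen")  # 0.5 ml
#' @export
region_volume_ml <- function(v, code) {
  stopifnot(inherits(v, "labeled_volume"))
  code <- .resolve_code(code)
  sum(v$labels == code) * prod(v$spacing) / 1000
}

#' Mean attenuation over a labeled ROI
#'
#' @param v a [labeled_volume].
#' @param code region code or name; the region must be non-empty.
#' @return mean HU over the region's voxels.
#' @export
roi_mean_hu <- function(v, code) {
  stopifnot(inherits(v, "labeled_volume"))
  code <- .resolve_code(code)
  sel <- v$labels == code
  if (!any(sel)) {
    stop_lsvar("empty_roi", sprintf("region code %d has no voxels", code))
  }
  mean(v$hu[sel])
}

#' Extract per-patient measurements from a labeled volume
#'
#' Emulates the reading-workstation step: segmental volumes by voxel
#' counting (segments I--III summed into the left-lobe volume, IV--VIII
#' into the right-lobe volume), splenic volume from the spleen label, and
#' vein/IVC attenuations as ROI means.  The veins are considered
#' contrasted iff any hepatic-vein voxels are labeled.
#'
#' @param v a [labeled_volume]; all eight Couinaud segment labels and the
#'   IVC label must be present.
#' @return a list with elements `volumes` (`vol_I_III_ml`,
#'   `vol_IV_VIII_ml`, `splenic_volume_ml`) and `attenuation` (`vein_hu`,
#'   `ivc_hu`, `veins_contrasted`).
#' @seealso [score_patient()] for turning the measurements into scores.
#' @export
measure_patient <- function(v) {
  stopifnot(inherits(v, "labeled_volume"))
  tab <- label_codes()
  seg_names <- paste0("segment_", c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"))
  seg_vols <- vapply(seg_names, function(nm) region_volume_ml(v, nm), numeric(1))
  missing <- seg_names[seg_vols == 0]
  if (length(missing) > 0) {
    stop_lsvar(
      "measurement_error",
      sprintf("liver segment label(s) missing from the volume: %s (codes %s)",
              paste(missing, collapse = ", "),
              paste(tab[missing], collapse = ", "))
    )
  }
  if (!any(v$labels == tab[["ivc"]])) {
    stop_lsvar("measurement_error", "IVC label (code 21) missing from the volume")
  }
  veins_contrasted <- any(v$labels == tab[["hepatic_veins"]])
  list(
    volumes = list(
      vol_I_III_ml = sum(seg_vols[1:3]),
      vol_IV_VIII_ml = sum(seg_vols[4:8]),
      splenic_volume_ml = region_volume_ml(v, "spleen")
    ),
    attenuation = list(
      vein_hu = if (veins_contrasted) roi_mean_hu(v, "hepatic_veins") else NA_real_,
      ivc_hu = roi_mean_hu(v, "ivc"),
      veins_contrasted = veins_contrasted
    )
  )
}

#' Specify a synthetic CT phantom
#'
#' Target volumes, attenuation levels and grid geometry for
#' [generate_phantom()].  Defaults give a cohort-scale liver on a 2 mm
#' grid.
#'
#' @param vol_I_III_ml,vol_IV_VIII_ml target left-lobe (segments I--III)
#'   and right-lobe (segments IV--VIII) volumes (ml).  Split evenly across
#'   the 3 and 5 segment labels.
#' @param splenic_volume_ml target splenic volume (ml).
#' @param vein_hu,ivc_hu,parenchyma_hu,spleen_hu,background_hu region
#'   attenuation levels (HU).
#' @param veins_contrasted logical; `FALSE` omits the hepatic-vein label
#'   entirely (the phantom analogue of veins with no visible contrast).
#' @param vein_volume_ml,ivc_volume_ml vessel region sizes (ml).
#' @param shape grid dimensions (voxels) along the three axes.
#' @param spacing voxel edge lengths (mm).
#' @param noise_sd spread of the additive zero-mean Gaussian HU noise;
#'   values are clipped to the valid HU range.  0 disables noise.
#' @param seed RNG seed making the phantom deterministic.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(vol_I_III_ml, vol_IV_VIII_ml,
                         splenic_volume_ml = 229,
                         vein_hu = 110, ivc_hu = 110,
                         parenchyma_hu = 105, spleen_hu = 95,
                         background_hu = -75,
                         veins_contrasted = TRUE,
                         vein_volume_ml = 9, ivc_volume_ml = 12,
                         shape = c(160, 112, 112), spacing = c(2, 2, 2),
                         noise_sd = 3, seed = 1L) {
  vols <- c(vol_I_III_ml, vol_IV_VIII_ml, splenic_volume_ml,
            vein_volume_ml, ivc_volume_ml)
  if (any(!is.finite(vols)) || any(vols <= 0)) {
    stop_lsvar("invalid_volume", "all target volumes must be finite and > 0 ml")
  }
  check_finite_hu(c(vein_hu, ivc_hu, parenchyma_hu, spleen_hu, background_hu),
                  "phantom attenuation levels")
  if (length(shape) != 3 || any(shape < 8) || any(shape != as.integer(shape))) {
    stop_lsvar("invalid_volume", "`shape` must be 3 integer grid dimensions >= 8")
  }
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_lsvar("invalid_volume", "`spacing` must be 3 positive edge lengths (mm)")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop_lsvar("invalid_volume", "`noise_sd` must be >= 0")
  }
  structure(
    list(
      vol_I_III_ml = vol_I_III_ml, vol_IV_VIII_ml = vol_IV_VIII_ml,
      splenic_volume_ml = splenic_volume_ml,
      vein_hu = vein_hu, ivc_hu = ivc_hu,
      parenchyma_hu = parenchyma_hu, spleen_hu = spleen_hu,
      background_hu = background_hu,
      veins_contrasted = isTRUE(veins_contrasted),
      vein_volume_ml = vein_volume_ml, ivc_volume_ml = ivc_volume_ml,
      shape = as.integer(shape), spacing = as.numeric(spacing),
      noise_sd = noise_sd, seed = seed
    ),
    class = "phantom_spec"
  )
}

# Split 1:n into `parts` contiguous index blocks.
.axis_blocks <- function(n, parts) {
  cut_pts <- floor(seq(0, n, length.out = parts + 1))
  lapply(seq_len(parts), function(i) (cut_pts[i] + 1L):cut_pts[i + 1L])
}

#' Generate a synthetic labeled CT phantom
#'
#' Builds a [labeled_volume] whose regions are connected, non-overlapping
#' ellipsoid-based blobs hitting the target volumes of the [phantom_spec].
#' Each region is voxelized by selecting exactly the target number of
#' voxels in increasing ellipsoidal-norm order around the region centre,
#' so measured voxel-count volumes agree with the targets to within one
#' voxel.  Attenuations are the spec levels plus seeded zero-mean Gaussian
#' noise, clipped to the valid HU range.  The output is fully determined
#' by the spec (including its seed).
#'
#' @param spec a [phantom_spec].
#' @return a [labeled_volume].
#' @examples
#' p <- generate_phantom(phantom_spec(80, 400, splenic_volume_ml = 60,
#'                                    shape = c(96, 64, 64), seed = 7))
#' region_volume_ml(p, "spleen")
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  tab <- label_codes()
  shape <- spec$shape
  spacing <- spec$spacing
  vox_ml <- prod(spacing) / 1000

  # 3 x 2 x 2 partition of the grid: one cell per region (12 cells,
  # 11 regions at most).
  blocks <- list(
    .axis_blocks(shape[1], 3),
    .axis_blocks(shape[2], 2),
    .axis_blocks(shape[3], 2)
  )
  cells <- expand.grid(i = 1:3, j = 1:2, k = 1:2)

  regions <- data.frame(
    name = c(paste0("segment_", c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")),
             "spleen", "hepatic_veins", "ivc"),
    stringsAsFactors = FALSE
  )
  regions$code <- unname(tab[regions$name])
  regions$target_ml <- c(
    rep(spec$vol_I_III_ml / 3, 3),
    rep(spec$vol_IV_VIII_ml / 5, 5),
    spec$splenic_volume_ml, spec$vein_volume_ml, spec$ivc_volume_ml
  )
  regions$hu <- c(
    rep(spec$parenchyma_hu, 8),
    spec$spleen_hu, spec$vein_hu, spec$ivc_hu
  )
  if (!spec$veins_contrasted) {
    regions <- regions[regions$name != "hepatic_veins", ]
  }

  # Mild fixed anisotropy so blobs are ellipsoids, not spheres; shape
  # factors multiply to 1 so the analytic volume is preserved.  The
  # smallest factor sits on the x axis, which the cell layout splits
  # three ways.
  sf <- c(1 / 1.08, 1.08, 1.0)

  labels <- array(0L, dim = shape)
  hu <- array(spec$background_hu, dim = shape)

  for (r in seq_len(nrow(regions))) {
    cell <- cells[r, ]
    ix <- blocks[[1]][[cell$i]]
    iy <- blocks[[2]][[cell$j]]
    iz <- blocks[[3]][[cell$k]]
    # cell extent and centre in mm
    half_mm <- c(length(ix), length(iy), length(iz)) * spacing / 2
    centre_mm <- c(mean(ix), mean(iy), mean(iz)) * spacing

    target_n <- max(1L, as.integer(round(regions$target_ml[r] / vox_ml)))
    r_mm <- (3 * regions$target_ml[r] * 1000 / (4 * pi))^(1 / 3)
    semi_mm <- r_mm * sf
    if (any(semi_mm > half_mm)) {
      stop_lsvar(
        "capacity_error",
        sprintf(
          "region %s (%.0f ml) does not fit its grid cell (needs semi-axes %s mm, cell half-widths %s mm)",
          regions$name[r], regions$target_ml[r],
          paste(sprintf("%.1f", semi_mm), collapse = "/"),
          paste(sprintf("%.1f", half_mm), collapse = "/")
        )
      )
    }

    # Ellipsoidal norm of every voxel centre in the cell; take exactly
    # target_n voxels in increasing-norm order (stable order(): ties break
    # by linear index, so the construction is deterministic).
    dx <- (ix * spacing[1] - centre_mm[1]) / semi_mm[1]
    dy <- (iy * spacing[2] - centre_mm[2]) / semi_mm[2]
    dz <- (iz * spacing[3] - centre_mm[3]) / semi_mm[3]
    d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
    sel <- order(d2)[seq_len(min(target_n, length(d2)))]
    if (length(sel) < target_n) {
      stop_lsvar(
        "capacity_error",
        sprintf("region %s needs %d voxels but its cell only has %d",
                regions$name[r], target_n, length(d2))
      )
    }
    # map cell-local linear indices back to grid indices
    arr_idx <- arrayInd(sel, .dim = c(length(ix), length(iy), length(iz)))
    gi <- cbind(ix[arr_idx[, 1]], iy[arr_idx[, 2]], iz[arr_idx[, 3]])
    labels[gi] <- regions$code[r]
    hu[gi] <- regions$hu[r]
  }

  if (spec$noise_sd > 0) {
    hu <- with_seed(spec$seed, {
      hu + array(stats::rnorm(length(hu), 0, spec$noise_sd), dim = shape)
    })
    hu[hu < HU_MIN] <- HU_MIN
    hu[hu > HU_MAX] <- HU_MAX
  }

  labeled_volume(hu, labels, spacing = spacing,
                 meta = list(seed = spec$seed, spec = unclass(spec)))
}

#' Write / read a labeled volume as a NIfTI pair
#'
#' `write_phantom()` stores the HU and label maps as two gzipped NIfTI
#' files (`<prefix>_hu.nii.gz`, `<prefix>_labels.nii.gz`) with identical
#' geometry, plus a JSON sidecar (`<prefix>_meta.json`) carrying the label
#' code table, the voxel spacing and any metadata.  `read_phantom()`
#' validates that the pair agrees in shape and spacing.
#'
#' @param v a [labeled_volume].
#' @param prefix path prefix for the three files.
#' @return `write_phantom()` returns `prefix` invisibly; `read_phantom()`
#'   returns a [labeled_volume].
#' @export
write_phantom <- function(v, prefix) {
  stopifnot(inherits(v, "labeled_volume"))
  hu_img <- RNifti::asNifti(v$hu)
  RNifti::pixdim(hu_img) <- v$spacing
  lab_img <- RNifti::asNifti(v$labels)
  RNifti::pixdim(lab_img) <- v$spacing
  RNifti::writeNifti(hu_img, paste0(prefix, "_hu.nii.gz"))
  RNifti::writeNifti(lab_img, paste0(prefix, "_labels.nii.gz"),
                     datatype = "int16")
  jsonlite::write_json(
    list(code_table = as.list(label_codes()), spacing_mm = v$spacing,
         meta = v$meta),
    paste0(prefix, "_meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(prefix)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  hu_path <- paste0(prefix, "_hu.nii.gz")
  lab_path <- paste0(prefix, "_labels.nii.gz")
  if (!file.exists(hu_path) || !file.exists(lab_path)) {
    stop_lsvar("io_error", sprintf("NIfTI pair not found at prefix '%s'", prefix))
  }
  hu_img <- RNifti::readNifti(hu_path)
  lab_img <- RNifti::readNifti(lab_path)
  if (!identical(dim(hu_img), dim(lab_img))) {
    stop_lsvar("invalid_volume", "HU and label volumes disagree in shape")
  }
  sp_hu <- RNifti::pixdim(hu_img)[1:3]
  sp_lab <- RNifti::pixdim(lab_img)[1:3]
  if (max(abs(sp_hu - sp_lab)) > 1e-6) {
    stop_lsvar("invalid_volume", "HU and label volumes disagree in voxel spacing")
  }
  meta <- list()
  meta_path <- paste0(prefix, "_meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)$meta %||% list()
  }
  labeled_volume(
    hu = array(as.numeric(hu_img), dim = dim(hu_img)),
    labels = array(as.integer(lab_img), dim = dim(lab_img)),
    spacing = as.numeric(sp_hu),
    meta = meta
  )
}
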