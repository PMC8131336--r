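make_volume <- function(shape = c(20, 20, 20), spacing = c(1, 1, 1)) {
  labeled_volume(array(0, shape), array(0L, shape), spacing = spacing)
}

test_that("region volume is voxel count times voxel volume, 0 for absent labels", {
  codes <- label_codes()
  lab <- array(0L, c(10, 10, 10))
  lab[, , 1:10] <- 0L
  lab[1:10, 1:10, 1:10][1:1000] <- codes[["spleen"]]
  v <- labeled_volume(array(100, c(10, 10, 10)), lab, spacing = c(1, 1, 1))
  expect_equal(region_volume_ml(v, "spleen"), 1.0)
  v2 <- labeled_volume(array(100, c(10, 10, 10)), lab, spacing = c(0.7, 0.7, 1))
  expect_equal(region_volume_ml(v2, "spleen"), 0.49)
  expect_equal(region_volume_ml(v, "segment_I"), 0.0)
  expect_equal(region_volume_ml(v, codes[["spleen"]]), 1.0)  # numeric code too
  expect_error(region_volume_ml(v, 99), class = "lsvar_invalid_volume")
})

test_that("labeled_volume rejects shape mismatches and unknown codes", {
  expect_error(
    labeled_volume(array(0, c(4, 4, 4)), array(0L, c(4, 4, 5))),
    class = "lsvar_invalid_volume"
  )
  bad <- array(0L, c(4, 4, 4)); bad[1] <- 99L
  expect_error(labeled_volume(array(0, c(4, 4, 4)), bad),
               class = "lsvar_invalid_volume")
  expect_error(
    labeled_volume(array(0, c(4, 4, 4)), array(0L, c(4, 4, 4)),
                   spacing = c(1, 0, 1)),
    class = "lsvar_invalid_volume"
  )
})

test_that("ROI mean attenuation averages the labeled voxels", {
  v <- make_volume()
  v$labels[1:10] <- label_codes()[["ivc"]]
  v$hu[1:10] <- 100
  expect_equal(roi_mean_hu(v, "ivc"), 100)
  v$hu[1:5] <- 80; v$hu[6:10] <- 120
  expect_equal(roi_mean_hu(v, "ivc"), 100)
  expect_error(roi_mean_hu(v, "spleen"), class = "lsvar_empty_roi")
})

test_that("generated phantoms are deterministic and hit their target volumes", {
  spec <- phantom_spec(80, 400, splenic_volume_ml = 60,
                       shape = c(96, 64, 64), spacing = c(2, 2, 2), seed = 7)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$hu, p2$hu)

  ratio <- (region_volume_ml(p1, 1) + region_volume_ml(p1, 2) +
              region_volume_ml(p1, 3)) /
    sum(vapply(4:8, function(cd) region_volume_ml(p1, cd), numeric(1)))
  expect_equal(ratio, 0.2, tolerance = 0.01)
  expect_equal(region_volume_ml(p1, "spleen"), 60,
               tolerance = 2 * prod(p1$spacing) / 1000 / 60)
})

test_that("oversized targets raise a capacity error", {
  expect_error(
    generate_phantom(phantom_spec(1e6, 1e6, shape = c(64, 64, 64),
                                  spacing = c(1, 1, 1))),
    class = "lsvar_capacity_error"
  )
})

test_that("noiseless phantoms reproduce the spec attenuations exactly and volumes additively", {
  spec <- phantom_spec(60, 300, splenic_volume_ml = 50,
                       vein_hu = 100, ivc_hu = 100, parenchyma_hu = 105,
                       shape = c(96, 64, 64), spacing = c(2, 2, 2),
                       noise_sd = 0, seed = 3)
  p <- generate_phantom(spec)
  expect_equal(roi_mean_hu(p, "hepatic_veins"), 100)
  expect_equal(roi_mean_hu(p, "ivc"), 100)
  expect_equal(roi_mean_hu(p, "spleen"), spec$spleen_hu)
  # additivity: total liver volume equals the sum over the 8 segment codes
  seg_sum <- sum(vapply(1:8, function(cd) region_volume_ml(p, cd), numeric(1)))
  m <- measure_patient(p)
  expect_equal(m$volumes$vol_I_III_ml + m$volumes$vol_IV_VIII_ml, seg_sum)
})

test_that("measured phantoms round-trip through the scoring chain", {
  spec <- phantom_spec(333, 1237, splenic_volume_ml = 229,
                       vein_hu = 100, ivc_hu = 100, seed = 11)
  p <- generate_phantom(spec)
  m <- measure_patient(p)
  expect_equal(m$volumes$vol_I_III_ml, 333, tolerance = 0.01)
  expect_equal(m$volumes$vol_IV_VIII_ml, 1237, tolerance = 0.01)
  expect_identical(
    suppressWarnings(  # single pooled vein ROI -> expected subset warning
      classify_lvca(m$attenuation$vein_hu, m$attenuation$ivc_hu,
                    m$attenuation$veins_contrasted)
    ),
    2L
  )
  lsvr <- compute_lsvr(m$volumes$vol_I_III_ml, m$volumes$vol_IV_VIII_ml)
  expect_equal(lsvr, 333 / 1237, tolerance = 0.02)

  # phantom without a vein label reads as uncontrasted -> LVCA 4
  spec4 <- phantom_spec(80, 400, splenic_volume_ml = 60,
                        veins_contrasted = FALSE,
                        shape = c(96, 64, 64), spacing = c(2, 2, 2), seed = 5)
  m4 <- measure_patient(generate_phantom(spec4))
  expect_false(m4$attenuation$veins_contrasted)
  expect_identical(
    classify_lvca(m4$attenuation$vein_hu, m4$attenuation$ivc_hu,
                  m4$attenuation$veins_contrasted),
    4L
  )
})

test_that("measure_patient names missing liver segment labels", {
  v <- make_volume(c(24, 24, 24))
  v$labels[1:50] <- 1L
  v$labels[51:100] <- label_codes()[["ivc"]]
  err <- tryCatch(measure_patient(v), error = function(e) e)
  expect_s3_class(err, "lsvar_measurement_error")
  expect_match(conditionMessage(err), "segment_II")
})

test_that("NIfTI pairs round-trip shape, spacing, labels and HU", {
  spec <- phantom_spec(40, 200, splenic_volume_ml = 35,
                       shape = c(64, 48, 48), spacing = c(2, 2, 2.5),
                       seed = 9)
  p <- generate_phantom(spec)
  prefix <- file.path(withr::local_tempdir(), "phantom01")
  write_phantom(p, prefix)
  q <- read_phantom(prefix)
  expect_identical(q$labels, p$labels)
  expect_equal(q$spacing, p$spacing)
  expect_equal(q$hu, p$hu, tolerance = 1e-6)
  expect_error(read_phantom(file.path(tempdir(), "nope")),
               class = "lsvar_io_error")
})
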