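# Preprocessing: IO round trips, 8-bit conversion, segmentation, resampling,
# contour masking and sphere fitting.

test_that("TIFF and MHD stacks round-trip bit-exactly with voxel size", {
  set.seed(42)
  arr <- array(sample(0:255, 16^3, replace = TRUE), c(16, 16, 16))
  vol <- image_volume(arr, 39)
  tmp <- withr::local_tempdir()

  tif <- file.path(tmp, "vol.tif")
  write_stack(vol, tif, meta = list(seed = 42))
  back <- read_stack(tif)
  expect_identical(back$data, arr + 0)
  expect_equal(back$voxel_size, 39)

  mhd <- file.path(tmp, "vol.mhd")
  write_stack(vol, mhd)
  back2 <- read_stack(mhd)
  expect_identical(back2$data, arr + 0)
  expect_equal(back2$voxel_size, 39)

  # a stack of 3 slices of 4 x 5 has dims (4, 5, 3)
  small <- image_volume(array(7, c(4, 5, 3)), 39)
  f3 <- file.path(tmp, "small.tif")
  write_stack(small, f3)
  expect_identical(dim(read_stack(f3)$data), c(4L, 5L, 3L))

  # voxel size must come from the sidecar, never a silent default
  file.remove(paste0(f3, ".json"))
  expect_error(read_stack(f3), "sidecar")
})

test_that("to_8bit maps the window linearly with half-up rounding", {
  v <- image_volume(array(c(-1, 0, 0.5, 1, 2), c(5, 1, 1)), 39)
  out <- to_8bit(v, c(0, 1))
  expect_equal(as.vector(out$data), c(0, 0, 128, 255, 255))
  # identity on already-8-bit data
  v8 <- image_volume(array(0:255, c(256, 1, 1)), 39)
  expect_equal(to_8bit(v8, c(0, 255))$data, v8$data)
  expect_error(to_8bit(v, c(1, 1)), "window")
})

test_that("segment_bone thresholds, despeckles, and reports empty masks", {
  uni <- image_volume(array(120, c(8, 8, 8)), 39)
  expect_true(all(segment_bone(uni, threshold = 110)$data))

  # two components: 1000 voxels and 10 voxels; despeckle keeps the larger
  arr <- array(0, c(30, 30, 30))
  arr[2:11, 2:11, 2:11] <- 200          # 1000-voxel block
  arr[20:29, 20, 20] <- 200             # 10-voxel filament
  m <- segment_bone(image_volume(arr, 39), sigma = 0, threshold = 110)
  expect_equal(sum(m$data), 1000L)
  expect_false(any(m$data[20:29, 20, 20]))

  expect_error(segment_bone(image_volume(array(5, c(8, 8, 8)), 39)), "110")

  # idempotent on its own binarised output re-presented as {0, 255}
  v <- fx_vol64()
  m1 <- segment_bone(v)
  v2 <- image_volume(array(ifelse(m1$data, 255, 0), dim(m1$data)), 39)
  m2 <- segment_bone(v2)
  expect_identical(m1$data, m2$data)
})

test_that("resample_half halves dimensions and doubles the voxel size", {
  v <- image_volume(array(runif(20 * 22 * 30) * 255, c(20, 22, 30)), 39)
  h <- resample_half(v)
  expect_identical(dim(h$data), c(10L, 11L, 15L))
  expect_equal(h$voxel_size, 78)

  const <- image_volume(array(77, c(16, 16, 16)), 39)
  expect_true(all(resample_half(const)$data == 77))
  # halving twice on a 4n-sized constant volume preserves the constant
  expect_true(all(resample_half(resample_half(const))$data == 77))
  # block mean oracle on a tiny case
  v2 <- image_volume(array(1:8, c(2, 2, 2)), 39)
  expect_equal(as.vector(resample_half(v2)$data), mean(1:8))
})

test_that("bone_contour_mask closes gaps, fills cavities, and is extensive", {
  dims <- c(48, 48, 48)
  ball <- binary_mask(ball_array(dims, c(24, 24, 24), 14), 39)
  closed <- bone_contour_mask(ball, 4)
  expect_true(all(closed$data[ball$data]))          # extensive
  expect_lt(sum(closed$data) - sum(ball$data), 0.02 * sum(ball$data))

  # two plates 6 voxels apart bridge under closing radius 5, and the gap fills
  lat <- array(FALSE, c(40, 40, 40))
  lat[8:32, 8:32, 12:15] <- TRUE
  lat[8:32, 8:32, 22:25] <- TRUE
  latm <- binary_mask(lat, 39)
  out <- bone_contour_mask(latm, 5)
  expect_true(all(out$data[lat]))
  expect_true(all(out$data[15:25, 15:25, 16:21]))   # gap interior filled

  full <- binary_mask(array(TRUE, c(12, 12, 12)), 39)
  expect_warning(bone_contour_mask(full, 2), "faces")
})

test_that("best_fit_sphere recovers digitized balls and shifts equivariantly", {
  dims <- c(64, 64, 64)
  m <- binary_mask(ball_array(dims, c(32, 30, 31), 15), 39)
  fit <- best_fit_sphere(m)
  expect_lt(max(abs(fit$center - c(32, 30, 31))), 1)
  expect_lt(abs(fit$radius_vox - 15), 1)
  expect_equal(fit$radius_um, fit$radius_vox * 39)

  shifted <- binary_mask(ball_array(dims, c(37, 30, 31), 15), 39)
  fit2 <- best_fit_sphere(shifted)
  expect_lt(max(abs((fit2$center - fit$center) - c(5, 0, 0))), 0.35)

  # hemisphere: the boundary-driven fit stays near the full-sphere radius
  hemi <- ball_array(dims, c(32, 32, 20), 16)
  hemi[, , 1:20] <- FALSE
  fith <- best_fit_sphere(binary_mask(hemi, 39))
  expect_lt(abs(fith$radius_vox - 16), abs(fith$radius_vox - 8))

  tiny <- binary_mask(array(FALSE, c(8, 8, 8)), 39)
  tiny$data[4, 4, 4] <- TRUE
  expect_error(best_fit_sphere(tiny), "boundary")
})

test_that("region_from_sphere drops slices below the fitted center", {
  dims <- c(32, 32, 32)
  m <- binary_mask(array(TRUE, dims), 39)
  fit <- structure(list(center = c(15, 15, 15.2), radius_vox = 10,
                        radius_um = 390, rms_residual_um = 0),
                   class = "sphere_fit")
  reg <- region_from_sphere(m, fit)
  expect_false(any(reg$data[, , 1:15]))
  expect_true(all(reg$data[, , 16:32]))
})
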