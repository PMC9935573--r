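test_that("resampling an already-isotropic volume at its own spacing is the identity", {
  v <- vessel_volume(array(runif(10 * 12 * 14), c(10, 12, 14)), rep(0.7, 3))
  out <- resample_isotropic(v, 0.7)
  expect_identical(out$intensities, v$intensities)
})

test_that("anisotropic acquisition geometry resamples to the expected isotropic grid", {
  # in-plane 0.57 mm with 1.4 mm slices, the typical TOF-MRA anisotropy
  v <- vessel_volume(array(rnorm(20 * 20 * 15), c(20, 20, 15)),
                     c(0.57, 0.57, 1.4))
  out <- resample_isotropic(v, 0.57)
  expect_equal(out$spacing, rep(0.57, 3))
  expect_equal(dim(out$intensities)[3], floor((15 - 1) * 1.4 / 0.57) + 1)
  expect_equal(dim(out$intensities)[1:2], c(20L, 20L))
  # physical extent preserved within one voxel
  ext_in <- (dim(v$intensities) - 1) * v$spacing
  ext_out <- (dim(out$intensities) - 1) * out$spacing
  expect_true(all(abs(ext_in - ext_out) <= 0.57 + 1e-9))
})

test_that("constant volumes stay constant under resampling and coarse targets warn", {
  v <- vessel_volume(array(5, c(8, 8, 8)), rep(0.5, 3))
  out <- resample_isotropic(v, 0.4)
  expect_true(all(out$intensities == 5))
  expect_warning(resample_isotropic(v, 2.5), "coarser")
  expect_error(resample_isotropic(v, -1), "positive")
})

test_that("NIfTI I/O round-trips the grid and spacing and rejects non-3D input", {
  v <- vessel_volume(array(rnorm(6 * 7 * 8), c(6, 7, 8)), c(0.6, 0.7, 0.8))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$intensities, v$intensities, ignore_attr = TRUE)
  expect_equal(v2$spacing, v$spacing)
  # uncompressed accepted equivalently
  f2 <- withr::local_tempfile(fileext = ".nii")
  write_volume(v, f2)
  expect_equal(read_volume(f2)$intensities, v$intensities, ignore_attr = TRUE)
  # 4D input rejected
  f4 <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(0, c(4, 4, 4, 2)))
  RNifti::writeNifti(img, f4)
  expect_error(read_volume(f4), "3D")
  expect_error(read_volume("/nonexistent/file.nii"), "no such file")
})

test_that("volume construction validates spacing and dimensionality", {
  expect_error(vessel_volume(matrix(0, 3, 3), c(1, 1, 1)), "3D")
  expect_error(vessel_volume(array(0, c(3, 3, 3)), c(1, -1, 1)), "positive")
})
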