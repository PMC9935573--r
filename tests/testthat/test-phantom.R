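test_that("a constant-radius tube has true score zero and a Gaussian dip matches the integration oracle", {
  ph <- fixture("tube_plain", function() tube_phantom())
  expect_equal(ph$truth$tube$score, 0)

  ph2 <- fixture("tube_d50", function() tube_phantom(depth = 0.5))
  expected <- oracle_tube_score(3, 0.5, 2, ph2$truth$tube$length)
  # slightly above 50 * (depth correction for the reduced mean)
  expect_gt(ph2$truth$tube$score, 40)
  expect_equal(ph2$truth$tube$score, expected, tolerance = 1e-4)
})

test_that("phantom truth is independent of noise seed and voxel spacing", {
  t1 <- tube_phantom(depth = 0.4, noise_sd = 50, seed = 1)$truth$tube
  t2 <- tube_phantom(depth = 0.4, noise_sd = 50, seed = 2)$truth$tube
  expect_identical(t1$score, t2$score)
  expect_identical(t1$radius, t2$radius)
  # same continuous spec rasterized on a finer grid: identical truth
  t3 <- tube_phantom(depth = 0.4, spacing = 0.5)$truth$tube
  expect_equal(t1$score, t3$score, tolerance = 1e-9)
  # but the voxel noise differs between seeds
  v1 <- tube_phantom(depth = 0.4, noise_sd = 50, seed = 1)$volume$intensities
  v2 <- tube_phantom(depth = 0.4, noise_sd = 50, seed = 2)$volume$intensities
  expect_false(identical(v1, v2))
})

test_that("deeper narrowing strictly increases the true score", {
  scores <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                   function(d) tube_phantom(depth = d)$truth$tube$score, 0)
  expect_true(all(diff(scores) > 0))
})

test_that("invalid phantom specifications are rejected with informative errors", {
  expect_error(tube_phantom(depth = 1), "depth")
  expect_error(
    phantom_spec(artery_spec("a", rbind(c(0, 0, 0), c(100, 0, 0)), 3),
                 volume_shape = c(20, 20, 20)),
    "outside the volume")
  expect_error(
    phantom_spec(artery_spec("a", rbind(c(1, 1, 1), c(5, 5, 5)), 0.5),
                 voxel_spacing = c(0.6, 0.6, 0.6)),
    "twice the coarsest")
})

test_that("rasterized lumen boundary matches the analytic tube radius", {
  ph <- fixture("tube_plain", function() tube_phantom())
  # mid-tube slice: digital disk of radius 3 at 0.6 mm spacing
  sl <- ph$lumen[, , 35]
  area <- sum(sl) * 0.36
  expect_equal(2 * sqrt(area / pi), 6, tolerance = 0.05)
})

test_that("phantom NIfTI + truth sidecar round-trip preserves grid and scores", {
  ph <- fixture("tube_d50", function() tube_phantom(depth = 0.5))
  nii <- withr::local_tempfile(fileext = ".nii.gz")
  paths <- write_phantom(ph, nii)
  vol2 <- read_volume(paths[["volume"]])
  expect_equal(vol2$intensities, ph$volume$intensities,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(vol2$spacing, ph$volume$spacing)
  truth2 <- read_phantom_truth(paths[["truth"]])
  expect_equal(truth2$tube$score, ph$truth$tube$score, tolerance = 1e-9)
})
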