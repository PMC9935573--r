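tree_graph <- function() {
  fixture("tree_graph", function() {
    ph <- fixture("tree_plain", function() default_tree())
    seg <- segment_vessels(resample_isotropic(ph$volume, 0.5))
    sk <- skeletonize_mask(seg)
    list(graph = build_centerline_graph(sk), seg = seg)
  })
}

test_that("the basilar trunk and both PCAs are localized on the default tree", {
  g <- tree_graph()$graph
  ba <- extract_target_artery(g, "ba")
  expect_gt(ba$match_score, 0.5)
  # trunk: midline, ascending, below the junction
  expect_lt(max(abs(ba$points[, 1] - 18.9)), 2)
  lp <- extract_target_artery(g, "left_pca")
  rp <- extract_target_artery(g, "right_pca")
  expect_gt(mean(lp$points[, 1]), 18.9)  # subject-left on image-right (high x)
  expect_lt(mean(rp$points[, 1]), 18.9)
  expect_gte(min(diff(lp$arclength)), 0)  # arclength monotone
})

test_that("a graph lacking a caudal trunk raises artery-not-found with diagnostics", {
  # single horizontal tube high in the volume: nothing matches the BA prior
  ph <- tube_phantom(axis = "x")
  seg <- segment_vessels(ph$volume)
  g <- build_centerline_graph(skeletonize_mask(seg))
  expect_error(extract_target_artery(g, "ba"), "artery not found")
})

test_that("straightening a plain tube returns near-constant diameters at twice the radius", {
  ph <- fixture("tube_plain", function() tube_phantom())
  seg <- segment_vessels(resample_isotropic(ph$volume, 0.5))
  g <- build_centerline_graph(skeletonize_mask(seg))
  res <- score_single_vessel(ph$volume)
  expect_equal(res$S, 0, tolerance = 2)
  expect_equal(res$d_average, 6, tolerance = 0.3)
  expect_equal(res$d_min, 6, tolerance = 0.4)
})

test_that("a 50%-depth stenosis halves the minimum diameter", {
  ph <- fixture("tube_d50", function() tube_phantom(depth = 0.5))
  res <- score_single_vessel(ph$volume)
  expect_equal(res$d_min, 3, tolerance = 0.4)
  expect_equal(res$S, ph$truth$tube$score, tolerance = 5)
})

test_that("halving the straightening step barely changes the summary diameters", {
  ph <- fixture("tube_d50", function() tube_phantom(depth = 0.5))
  c1 <- pipeline_config()
  c2 <- pipeline_config(straighten = straighten_config(step_mm = 0.25))
  r1 <- score_single_vessel(ph$volume, c1)
  r2 <- score_single_vessel(ph$volume, c2)
  expect_lt(abs(r1$d_min - r2$d_min), 0.2)
  expect_lt(abs(r1$d_average - r2$d_average), 0.2)
})

test_that("the stenosis score follows the diameter-ratio arithmetic exactly", {
  r <- compute_stenosis_score(c(4, 4, 2, 4, 4))
  expect_equal(r$d_min, 2)
  expect_equal(r$d_average, 3.6)
  expect_equal(r$S, (1 - 2 / 3.6) * 100, tolerance = 1e-12)
  expect_equal(r$S, 44.4444, tolerance = 1e-4)
  expect_equal(as.character(r$grade), "<50%")

  const <- compute_stenosis_score(rep(3.3, 7))
  expect_equal(const$S, 0)
  expect_equal(as.character(const$grade), "<50%")

  # a score of exactly 50 belongs to the >=50% grade
  at50 <- compute_stenosis_score(c(2, 3, 4, 5, 6))
  expect_equal(at50$S, 50)
  expect_equal(as.character(at50$grade), ">=50%")

  expect_error(compute_stenosis_score(c(4, 2)), "fewer than 3")
})

test_that("scoring the default tree recovers the imposed left-PCA stenosis and spares the others", {
  st <- list(left_pca = data.frame(position = 0.5, depth = 0.5, width = 2))
  ph <- fixture("tree_lpca", function() default_tree(stenoses = st))
  rep <- suppressWarnings(score_posterior_circulation(ph$volume))
  expect_s3_class(rep$results$left_pca, "stenosis_result")
  expect_equal(rep$results$left_pca$S, ph$truth$left_pca$score, tolerance = 5)
  expect_lt(rep$results$ba$S, 5)
  expect_lt(rep$results$right_pca$S, 5)
  expect_equal(unname(rep$topology["junctions"]), 1L)
  # provenance is machine-readable and carries the resolved parameters
  expect_true(is.numeric(rep$provenance$threshold))
  expect_match(rep$provenance$config_hash, "^[0-9a-f]{32}$")
})

test_that("mirroring the fixture in x swaps the left/right PCA labels", {
  st <- list(left_pca = data.frame(position = 0.5, depth = 0.5, width = 2))
  ph_m <- fixture("tree_lpca_mirror",
                  function() default_tree(stenoses = st, mirror = TRUE))
  rep_m <- suppressWarnings(score_posterior_circulation(ph_m$volume))
  # construction-left is now on image-left = subject-right
  expect_gt(rep_m$results$right_pca$S, 30)
  expect_lt(rep_m$results$left_pca$S, 10)
})

test_that("an empty volume propagates the empty-segmentation error", {
  v <- vessel_volume(array(0, c(20, 20, 20)) + rnorm(8000, 0, 1), rep(0.6, 3))
  expect_error(
    score_single_vessel(v, pipeline_config(
      segment = segment_config(threshold_mode = "absolute", threshold_value = 50))),
    "empty segmentation")
})

test_that("pipeline scores are equivariant to 90-degree axis permutations of the anatomy", {
  st_scores <- vapply(c("z", "x", "y"), function(ax) {
    ph <- tube_phantom(depth = 0.45, axis = ax)
    suppressWarnings(score_single_vessel(ph$volume))$S
  }, 0)
  expect_lte(max(st_scores) - min(st_scores), 2)
})

test_that("pipeline scores increase monotonically with imposed depth (noise-free)", {
  s <- vapply(c(0.2, 0.45, 0.7), function(d)
    suppressWarnings(score_single_vessel(tube_phantom(depth = d)$volume))$S, 0)
  expect_true(all(diff(s) > 0))
})
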