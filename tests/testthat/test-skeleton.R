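test_that("a straight tube thins to a near-axial curve with two endpoints and one edge", {
  ph <- fixture("tube_plain", function() tube_phantom())
  seg <- segment_vessels(ph$volume)
  sk <- skeletonize_mask(seg)
  g <- build_centerline_graph(sk)
  topo <- graph_topology(g)
  expect_equal(unname(topo["endpoints"]), 2L)
  expect_equal(unname(topo["junctions"]), 0L)
  expect_equal(unname(topo["edges"]), 1L)

  # Hausdorff distance of skeleton voxels to the true axis within ~1 voxel
  vox <- which(sk$mask, arr.ind = TRUE)
  mm <- sweep(vox - 1, 2, sk$spacing, "*")
  axis_xy <- ph$truth$tube$centerline[1, 1:2]
  off <- sqrt((mm[, 1] - axis_xy[1])^2 + (mm[, 2] - axis_xy[2])^2)
  expect_lte(max(off), max(sk$spacing) * sqrt(2) + 1e-9)
})

test_that("a single-voxel mask is its own skeleton", {
  a <- array(FALSE, c(9, 9, 9)); a[5, 5, 5] <- TRUE
  sk <- skeletonize_mask(a, spacing = rep(0.6, 3), prune_mm = 0)
  expect_identical(sk$mask, a)
  g <- build_centerline_graph(sk)
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(g$nodes$type, "isolated")
})

test_that("the Y-tree fixture skeletonizes to exactly one junction and three endpoint tips", {
  ph <- fixture("tree_plain", function() default_tree())
  seg <- segment_vessels(resample_isotropic(ph$volume, 0.5))
  sk <- skeletonize_mask(seg)
  g <- build_centerline_graph(sk)
  topo <- graph_topology(g)
  expect_equal(unname(topo["endpoints"]), 3L)
  expect_equal(unname(topo["junctions"]), 1L)
  expect_equal(unname(topo["edges"]), 3L)
})

test_that("edge lengths are physical and bounded below by the endpoint distance", {
  # synthetic straight digital line, 20 mm at 0.5 mm steps
  a <- array(FALSE, c(9, 9, 45))
  a[5, 5, 3:43] <- TRUE
  g <- build_centerline_graph(a, spacing = rep(0.5, 3))
  expect_equal(length(g$edges), 1L)
  expect_equal(g$edges[[1]]$length_mm, 20, tolerance = 0.5 * sqrt(3) / 20)
  for (e in g$edges) {
    ends <- e$points_mm[c(1, nrow(e$points_mm)), ]
    expect_gte(e$length_mm + 1e-9, sqrt(sum(diff(ends)^2)))
  }

  # a diagonal line is longer than its axial projection
  b <- array(FALSE, c(30, 30, 30))
  for (i in 5:25) b[i, i, i] <- TRUE
  g2 <- build_centerline_graph(b, spacing = rep(0.5, 3))
  expect_equal(g2$edges[[1]]$length_mm, 20 * sqrt(3) / 2, tolerance = 0.01)
})

test_that("short spurs are pruned while long branches survive", {
  a <- array(FALSE, c(40, 15, 15))
  a[3:38, 8, 8] <- TRUE          # 21 mm trunk at 0.6 mm
  a[20, 9:11, 8] <- TRUE         # 1.8 mm spur
  sk0 <- structure(list(mask = a, spacing = rep(0.6, 3), prune_mm = 3),
                   class = "skeleton")
  pruned <- stenoscore:::prune_skeleton(sk0, 3)
  g <- build_centerline_graph(pruned)
  expect_equal(unname(graph_topology(g)["endpoints"]), 2L)
  expect_equal(unname(graph_topology(g)["junctions"]), 0L)
})

test_that("every skeleton voxel lies on exactly one edge chain or node", {
  ph <- fixture("tree_plain", function() default_tree())
  seg <- segment_vessels(resample_isotropic(ph$volume, 0.5))
  sk <- skeletonize_mask(seg)
  g <- build_centerline_graph(sk)
  d <- dim(sk$mask)
  covered <- integer(0)
  for (e in g$edges)
    covered <- c(covered, stenoscore:::chain_linear_index(e$chain, d))
  for (i in seq_len(nrow(g$nodes)))
    covered <- c(covered, stenoscore:::chain_linear_index(g$nodes$voxel[[i]], d))
  expect_setequal(unique(covered), which(sk$mask))
  # interior chain voxels are not shared between edges
  interior <- unlist(lapply(g$edges, function(e) {
    idx <- stenoscore:::chain_linear_index(e$chain, d)
    idx[-c(1, length(idx))]
  }))
  expect_false(any(duplicated(interior)))
})
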