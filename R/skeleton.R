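#' Skeletonize a binary vessel mask
#'
#' Topology-preserving sequential thinning to a 1-voxel-wide (26-connected)
#' curve skeleton. Voxels are removed only when they are simple points, in
#' increasing order of the interior Euclidean distance transform so the
#' retained curve stays on the medial axis; curve endpoints are never
#' removed. Skeleton spurs shorter than `prune_mm` that hang off a junction
#' are then pruned at the graph level.
#'
#' @param mask a [segment_vessels()] result, or a logical 3D array with
#'   `spacing` supplied.
#' @param spacing mm triple (ignored when `mask` is a `segmentation_mask`).
#' @param prune_mm spur-prune length in mm (0 disables pruning).
#' @return an object of class `skeleton`: list with `mask` (logical array of
#'   skeleton voxels), `spacing`, and `prune_mm`.
#' @export
skeletonize_mask <- function(mask, spacing = NULL, prune_mm = 3) {
  if (inherits(mask, "segmentation_mask")) {
    spacing <- mask$spacing
    mask <- mask$mask
  }
  stopifnot(is.array(mask), length(dim(mask)) == 3L, !is.null(spacing))
  if (!any(mask)) stop("cannot skeletonize an empty mask")
  d <- dim(mask)
  pri <- sqrt(cpp_edt_sq(as.logical(mask), as.integer(d), as.numeric(spacing)))
  skel <- array(cpp_thin(as.logical(mask), as.integer(d), pri), dim = d)
  out <- structure(list(mask = skel, spacing = as.numeric(spacing),
                        prune_mm = prune_mm),
                   class = "skeleton")
  if (prune_mm > 0) out <- prune_skeleton(out, prune_mm)
  out
}

#' @export
print.skeleton <- function(x, ...) {
  cat("<skeleton> ", sum(x$mask), " voxels @ ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

# Remove terminal edges shorter than prune_mm that attach to a junction;
# iterate because pruning can simplify junctions.
prune_skeleton <- function(skel, prune_mm, max_iter = 10L) {
  for (it in seq_len(max_iter)) {
    g <- build_centerline_graph(skel)
    deg <- graph_node_degree(g)
    drop_idx <- NULL
    for (e in g$edges) {
      a <- deg[e$from]; b <- deg[e$to]
      if (e$length_mm >= prune_mm) next
      term <- (a == 1L && b >= 3L) || (b == 1L && a >= 3L)
      if (!term) next
      chain <- e$chain
      keep_node <- if (a >= 3L) e$from else e$to
      keep_vox <- g$nodes$voxel[g$nodes$id == keep_node][[1]]
      lin <- chain_linear_index(chain, dim(skel$mask))
      lin <- setdiff(lin, chain_linear_index(keep_vox, dim(skel$mask)))
      drop_idx <- c(drop_idx, lin)
    }
    if (length(drop_idx) == 0L) break
    skel$mask[drop_idx] <- FALSE
    # pruning can leave redundant attachment voxels at the junction; one more
    # thinning pass removes any that became simple and non-terminal
    d <- dim(skel$mask)
    skel$mask <- array(cpp_thin(as.logical(skel$mask), as.integer(d),
                                numeric(prod(d))), dim = d)
  }
  skel
}

chain_linear_index <- function(chain, d) {
  chain <- matrix(chain, ncol = 3)
  chain[, 1] + d[1] * (chain[, 2] - 1L) + d[1] * d[2] * (chain[, 3] - 1L)
}

graph_node_degree <- function(g) {
  deg <- setNames(integer(nrow(g$nodes)), g$nodes$id)
  for (e in g$edges) {
    deg[e$from] <- deg[e$from] + 1L
    deg[e$to] <- deg[e$to] + 1L
  }
  deg
}

#' Build a centerline topology graph from a skeleton
#'
#' Classifies skeleton voxels by their number of 26-neighbours (1 =
#' endpoint, >= 3 = junction; adjacent junction voxels are collapsed into a
#' single junction node), then traces the voxel chains between nodes as
#' edges with physical lengths (sum of inter-voxel steps in mm). Cycles are
#' permitted; self-loop edges are collapsed (dropped).
#'
#' @param skeleton a [skeletonize_mask()] result, or a logical 3D array with
#'   `spacing` supplied.
#' @param spacing mm triple when a bare array is given.
#' @return an object of class `centerline_graph`: `nodes` data frame (`id`,
#'   `type`, `x`, `y`, `z` voxel indices, `voxel` list of member voxels, mm
#'   coordinates) and `edges` list (`from`, `to`, `chain` voxel matrix,
#'   `points_mm`, `length_mm`), plus the grid geometry.
#' @export
build_centerline_graph <- function(skeleton, spacing = NULL) {
  if (inherits(skeleton, "skeleton")) {
    spacing <- skeleton$spacing
    skel <- skeleton$mask
  } else {
    skel <- skeleton
  }
  stopifnot(is.array(skel), length(dim(skel)) == 3L, !is.null(spacing))
  d <- dim(skel)
  vox <- which(skel)
  if (length(vox) == 0L) stop("empty skeleton")
  idx <- arrayInd(vox, d)
  n <- length(vox)
  in_skel <- array(0L, dim = d)
  in_skel[vox] <- seq_len(n)

  nb_offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb_offsets <- nb_offsets[rowSums(abs(nb_offsets)) > 0, ]

  neighbours_of <- function(i) {
    p <- idx[i, ]
    cand <- sweep(nb_offsets, 2, p, "+")
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
          cand[, 2] >= 1 & cand[, 2] <= d[2] &
          cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    ids <- in_skel[cand]
    ids[ids > 0L]
  }
  nbrs <- lapply(seq_len(n), neighbours_of)
  deg <- lengths(nbrs)

  is_node_vox <- deg != 2L
  # collapse 26-adjacent junction voxels into single nodes
  node_of <- integer(n)
  nodes <- list()
  nid <- 0L
  for (i in seq_len(n)) {
    if (!is_node_vox[i] || node_of[i] > 0L) next
    nid <- nid + 1L
    members <- i
    if (deg[i] >= 3L) {
      stack <- i
      node_of[i] <- nid
      while (length(stack)) {
        c0 <- stack[[1]]; stack <- stack[-1]
        for (q in nbrs[[c0]]) {
          if (deg[q] >= 3L && node_of[q] == 0L) {
            node_of[q] <- nid
            members <- c(members, q)
            stack <- c(stack, q)
          }
        }
      }
    } else {
      node_of[i] <- nid
    }
    type <- if (deg[i] == 0L) "isolated" else if (deg[i] == 1L) "endpoint" else "junction"
    rep_i <- members[which.max(deg[members])]
    nodes[[nid]] <- list(id = nid, type = type, members = members, rep = rep_i)
  }

  # trace edges between node voxels through degree-2 chains
  edges <- list()
  used_step <- new.env(hash = TRUE)
  step_key <- function(a, b) paste0(a, "_", b)
  sp <- as.numeric(spacing)
  for (nd in nodes) {
    for (m in nd$members) {
      for (r in nbrs[[m]]) {
        if (node_of[r] == node_of[m] && node_of[r] > 0L) next  # inside same node
        key <- step_key(m, r)
        if (!is.null(used_step[[key]])) next
        chain <- c(m)
        prev <- m
        cur <- r
        used_step[[key]] <- TRUE
        while (node_of[cur] == 0L) {
          chain <- c(chain, cur)
          nx <- setdiff(nbrs[[cur]], prev)
          if (length(nx) == 0L) break  # degenerate; treat cur as terminus
          prev <- cur
          cur <- nx[[1]]
        }
        chain <- c(chain, cur)
        used_step[[step_key(cur, prev)]] <- TRUE
        from <- node_of[m]
        to <- node_of[cur]
        if (to == 0L) to <- from  # degenerate open chain
        if (from == to && length(chain) <= 3L) next  # self-loop: collapse
        pts <- idx[chain, , drop = FALSE]
        mm <- sweep(pts - 1, 2, sp, "*")
        len <- if (nrow(mm) > 1L) sum(sqrt(rowSums(diff(mm)^2))) else 0
        if (from == to) next  # larger self-loops also collapsed
        edges[[length(edges) + 1L]] <- list(from = from, to = to, chain = pts,
                                            points_mm = mm, length_mm = len)
      }
    }
  }

  # pure cycles (all voxels degree 2) have no nodes: promote one voxel per
  # unvisited component so the cycle is represented
  visited <- logical(n)
  visited[node_of > 0L] <- TRUE
  for (e in edges) visited[in_skel[chain_linear_index(e$chain, d)]] <- TRUE
  for (i in seq_len(n)) {
    if (visited[i] || deg[i] != 2L) next
    nid <- nid + 1L
    node_of[i] <- nid
    nodes[[nid]] <- list(id = nid, type = "cycle", members = i, rep = i)
    # trace the loop once
    r <- nbrs[[i]][[1]]
    chain <- c(i); prev <- i; cur <- r
    while (cur != i) {
      chain <- c(chain, cur)
      visited[cur] <- TRUE
      nx <- setdiff(nbrs[[cur]], prev)
      if (length(nx) == 0L) break
      prev <- cur; cur <- nx[[1]]
    }
    visited[i] <- TRUE
    pts <- idx[c(chain, i), , drop = FALSE]
    mm <- sweep(pts - 1, 2, sp, "*")
    edges[[length(edges) + 1L]] <- list(from = nid, to = nid, chain = pts,
                                        points_mm = mm,
                                        length_mm = sum(sqrt(rowSums(diff(mm)^2))))
  }

  nodes_df <- data.frame(
    id = vapply(nodes, `[[`, 0L, "id"),
    type = vapply(nodes, `[[`, "", "type"),
    x = vapply(nodes, function(nd) idx[nd$rep, 1], 0L),
    y = vapply(nodes, function(nd) idx[nd$rep, 2], 0L),
    z = vapply(nodes, function(nd) idx[nd$rep, 3], 0L)
  )
  nodes_df$mm_x <- (nodes_df$x - 1) * sp[1]
  nodes_df$mm_y <- (nodes_df$y - 1) * sp[2]
  nodes_df$mm_z <- (nodes_df$z - 1) * sp[3]
  nodes_df$voxel <- lapply(nodes, function(nd) idx[nd$members, , drop = FALSE])

  structure(list(nodes = nodes_df, edges = edges, spacing = sp, dim = d),
            class = "centerline_graph")
}

#' @export
print.centerline_graph <- function(x, ...) {
  tt <- table(x$nodes$type)
  cat("<centerline_graph> ", nrow(x$nodes), " nodes (",
      paste(sprintf("%s: %d", names(tt), tt), collapse = ", "), "), ",
      length(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Count endpoints and junctions of a centerline graph
#'
#' @param graph a [build_centerline_graph()] result.
#' @return named integer vector with `endpoints`, `junctions`, `edges`.
#' @export
graph_topology <- function(graph) {
  stopifnot(inherits(graph, "centerline_graph"))
  c(endpoints = sum(graph$nodes$type == "endpoint"),
    junctions = sum(graph$nodes$type == "junction"),
    edges = length(graph$edges))
}
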