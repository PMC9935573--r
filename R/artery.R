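#' Anatomical prior for a posterior-circulation artery
#'
#' Priors localize each target artery in the centerline graph: an expected
#' seed region in volume-fraction coordinates, an expected orientation, and
#' a minimum length. The basilar artery runs near the midline in the caudal
#' half and ascends; each posterior cerebral artery leaves the bifurcation
#' laterally and superiorly. Laterality follows the radiological display
#' convention (subject-left on image-right, i.e. high x) unless
#' `left_is_high_x = FALSE`.
#'
#' @param artery_id one of `"ba"`, `"left_pca"`, `"right_pca"`.
#' @param left_is_high_x laterality convention flag.
#' @return list with `seed_frac`, `orientation`, `min_length_mm`, `side`.
#' @export
artery_prior <- function(artery_id = c("ba", "left_pca", "right_pca"),
                         left_is_high_x = TRUE) {
  artery_id <- match.arg(artery_id)
  lat <- if (left_is_high_x) 1 else -1
  switch(artery_id,
    ba = list(seed_frac = c(0.5, 0.5, 0.3), orientation = c(0, 0, 1),
              min_length_mm = 8, side = 0),
    left_pca = list(seed_frac = c(0.5 + 0.25 * lat, 0.55, 0.75),
                    orientation = unit_vector(c(0.65 * lat, 0.2, 0.73)),
                    min_length_mm = 8, side = lat),
    right_pca = list(seed_frac = c(0.5 - 0.25 * lat, 0.55, 0.75),
                     orientation = unit_vector(c(-0.65 * lat, 0.2, 0.73)),
                     min_length_mm = 8, side = -lat)
  )
}

edge_summary <- function(e) {
  mm <- e$points_mm
  dirv <- mm[nrow(mm), ] - mm[1, ]
  nd <- sqrt(sum(dirv^2))
  list(mean = colMeans(mm), dir = if (nd > 0) dirv / nd else c(0, 0, 0),
       length = e$length_mm)
}

#' Localize and extract a target artery from the centerline graph
#'
#' Each graph edge is scored as a weighted sum of (a) proximity of its
#' centroid to the prior seed point (`exp(-d/10 mm)`, weight 0.4), (b)
#' absolute orientation agreement with the prior direction (weight 0.4) and
#' (c) length adequacy (`min(1, length/min_length)`, weight 0.2). For the
#' paired arteries only edges whose centroid lies on the correct side of the
#' x midline are candidates, so mirroring the volume swaps the left/right
#' labels. The winning chain is returned oriented caudo-cranially.
#'
#' @param graph a [build_centerline_graph()] result.
#' @param artery_id `"ba"`, `"left_pca"` or `"right_pca"`.
#' @param prior override of [artery_prior()].
#' @param left_is_high_x laterality convention.
#' @param min_score minimum acceptable match score in `[0, 1]`.
#' @return an object of class `artery_path`: `artery_id`, `points` (mm
#'   matrix), `arclength`, `match_score`, `diagnostics`.
#' @export
extract_target_artery <- function(graph, artery_id, prior = NULL,
                                  left_is_high_x = TRUE, min_score = 0.35) {
  stopifnot(inherits(graph, "centerline_graph"))
  if (length(graph$edges) == 0L) stop("artery not found: graph has no edges")
  prior <- prior %||% artery_prior(artery_id, left_is_high_x)
  extent <- (graph$dim - 1) * graph$spacing
  seed <- prior$seed_frac * extent
  midline <- extent[1] / 2

  diag_rows <- lapply(seq_along(graph$edges), function(i) {
    es <- edge_summary(graph$edges[[i]])
    side_off <- es$mean[1] - midline
    side_ok <- prior$side == 0 || sign(side_off) == prior$side && abs(side_off) > 0.5
    s_seed <- exp(-sqrt(sum((es$mean - seed)^2)) / 10)
    s_orient <- abs(sum(es$dir * prior$orientation))
    s_len <- min(1, es$length / prior$min_length_mm)
    data.frame(edge = i, score = 0.4 * s_seed + 0.4 * s_orient + 0.2 * s_len,
               seed_term = s_seed, orient_term = s_orient, length_term = s_len,
               side_ok = side_ok, length_mm = es$length)
  })
  diag_df <- do.call(rbind, diag_rows)
  # hard orientation gate: a chain more than ~63 degrees off the expected
  # course is never this artery, whatever its other terms
  ok <- diag_df[diag_df$side_ok & diag_df$orient_term >= 0.45, , drop = FALSE]
  if (nrow(ok) == 0L || max(ok$score) < min_score) {
    stop("artery not found for '", artery_id, "'; candidate diagnostics:\n",
         paste(utils::capture.output(print(diag_df, row.names = FALSE)), collapse = "\n"))
  }
  best <- ok$edge[which.max(ok$score)]
  e <- graph$edges[[best]]
  mm <- e$points_mm
  if (mm[1, 3] > mm[nrow(mm), 3]) mm <- mm[rev(seq_len(nrow(mm))), , drop = FALSE]
  arc <- c(0, cumsum(sqrt(rowSums(diff(mm)^2))))
  structure(list(artery_id = artery_id, points = mm, arclength = arc,
                 match_score = max(ok$score), diagnostics = diag_df),
            class = "artery_path")
}

#' @export
print.artery_path <- function(x, ...) {
  cat("<artery_path> ", x$artery_id, ": ", nrow(x$points), " points, ",
      signif(max(x$arclength), 4), " mm (match score ",
      signif(x$match_score, 3), ")\n", sep = "")
  invisible(x)
}

#' Straightening configuration
#'
#' @param step_mm arclength sampling step between cross-sections.
#' @param window_mm half-width of the in-plane sampling window.
#' @param grid_step_mm in-plane sampling resolution (default: half the
#'   finest voxel spacing).
#' @param end_trim_mm sections within this distance of either terminus are
#'   excluded from the summary diameters.
#' @param smooth_sd_mm Gaussian smoothing of the centerline before tangent
#'   estimation.
#' @return a list of class `straighten_config`.
#' @export
straighten_config <- function(step_mm = 0.5, window_mm = 5, grid_step_mm = NULL,
                              end_trim_mm = 2, smooth_sd_mm = 1) {
  structure(list(step_mm = step_mm, window_mm = window_mm,
                 grid_step_mm = grid_step_mm, end_trim_mm = end_trim_mm,
                 smooth_sd_mm = smooth_sd_mm),
            class = "straighten_config")
}

gaussian_smooth_path <- function(mm, s, sd_mm) {
  if (sd_mm <= 0) return(mm)
  out <- mm
  for (i in seq_along(s)) {
    w <- exp(-(s - s[i])^2 / (2 * sd_mm^2))
    w <- w / sum(w)
    out[i, ] <- colSums(mm * w)
  }
  out
}

#' Straighten an artery and profile its diameters
#'
#' Walks the (smoothed) centerline at fixed arclength steps; at each step a
#' plane orthogonal to the local tangent is carried along by parallel
#' transport (rotation + translation of the cross-section into a common
#' frame). The lumen cross-section is the 4-connected in-plane region of
#' the mask containing the centerline point, sampled by nearest neighbour;
#' its equivalent-circle diameter is `2 * sqrt(area / pi)`. Sections whose
#' cross-section is empty are dropped with a warning (a hard error if more
#' than 20\% drop), and sections within `end_trim_mm` of either end are
#' excluded from the `d_min`/`d_average` summary.
#'
#' @param mask a [segment_vessels()] result, or logical array plus `spacing`.
#' @param path an [extract_target_artery()] result (or any `artery_path`).
#' @param config a [straighten_config()].
#' @param spacing mm triple when `mask` is a bare array.
#' @return an object of class `diameter_profile`: data frame with columns
#'   `s` (mm), `d` (mm), `retained`; attributes `d_min`, `d_average`,
#'   `artery_id`, `n_dropped`.
#' @export
straighten_artery <- function(mask, path, config = straighten_config(),
                              spacing = NULL) {
  if (inherits(mask, "segmentation_mask")) {
    spacing <- mask$spacing
    mask <- mask$mask
  }
  stopifnot(inherits(path, "artery_path"), is.array(mask), !is.null(spacing))
  d <- dim(mask)
  sp <- as.numeric(spacing)
  L <- max(path$arclength)
  if (L <= 0) stop("degenerate path of zero length")

  s_out <- seq(0, L, by = config$step_mm)
  pts <- sapply(1:3, function(a)
    approx(path$arclength, path$points[, a], xout = s_out, ties = "ordered")$y)
  pts <- matrix(pts, ncol = 3)
  pts <- gaussian_smooth_path(pts, s_out, config$smooth_sd_mm)

  ns <- length(s_out)
  tang <- matrix(0, ns, 3)
  for (i in seq_len(ns)) {
    i0 <- max(1, i - 1); i1 <- min(ns, i + 1)
    tang[i, ] <- unit_vector(pts[i1, ] - pts[i0, ])
  }
  # parallel-transported in-plane frame
  u <- matrix(0, ns, 3); v <- matrix(0, ns, 3)
  ref <- if (abs(tang[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u[1, ] <- unit_vector(ref - sum(ref * tang[1, ]) * tang[1, ])
  v[1, ] <- crossprod3(tang[1, ], u[1, ])
  for (i in 2:ns) {
    pu <- u[i - 1, ] - sum(u[i - 1, ] * tang[i, ]) * tang[i, ]
    if (sqrt(sum(pu^2)) < 1e-8) pu <- v[i - 1, ] - sum(v[i - 1, ] * tang[i, ]) * tang[i, ]
    u[i, ] <- unit_vector(pu)
    v[i, ] <- crossprod3(tang[i, ], u[i, ])
  }

  h <- config$grid_step_mm %||% (min(sp) / 2)
  # half-step shift keeps sample points off voxel boundaries (no rounding ties)
  mhalf <- max(2L, as.integer(floor(config$window_mm / h)))
  g <- h * (seq_len(2L * mhalf) - mhalf - 0.5)
  m <- length(g)
  ctr <- mhalf  # sample nearest the centerline point (offset -h/2)
  offs <- cbind(rep(g, m), rep(g, each = m))  # (a, b) in-plane offsets

  d_mm <- rep(NA_real_, ns)
  truncated <- FALSE
  for (i in seq_len(ns)) {
    P <- cbind(pts[i, 1] + offs[, 1] * u[i, 1] + offs[, 2] * v[i, 1],
               pts[i, 2] + offs[, 1] * u[i, 2] + offs[, 2] * v[i, 2],
               pts[i, 3] + offs[, 1] * u[i, 3] + offs[, 2] * v[i, 3])
    ix <- round(P[, 1] / sp[1]) + 1L
    iy <- round(P[, 2] / sp[2]) + 1L
    iz <- round(P[, 3] / sp[3]) + 1L
    inb <- ix >= 1L & ix <= d[1] & iy >= 1L & iy <= d[2] & iz >= 1L & iz <= d[3]
    val <- logical(nrow(P))
    val[inb] <- mask[cbind(ix[inb], iy[inb], iz[inb])]
    region <- cpp_region_from_seed_2d(val, c(m, m), ctr - 1L, ctr - 1L)
    area <- sum(region) * h * h
    if (area == 0) next  # dropped section
    rg <- matrix(region, m, m)
    if (any(rg[1, ]) || any(rg[m, ]) || any(rg[, 1]) || any(rg[, m])) truncated <- TRUE
    d_mm[i] <- 2 * sqrt(area / pi)
  }
  n_drop <- sum(is.na(d_mm))
  if (n_drop > 0.2 * ns)
    stop(sprintf("straightening failed: %d of %d cross-sections empty", n_drop, ns))
  if (n_drop > 0)
    warning(n_drop, " empty cross-section(s) dropped")
  if (truncated)
    warning("some cross-sections touch the sampling window border; enlarge `window_mm`")

  trim <- rep_len(config$end_trim_mm, 2L)  # (start, end) trims may differ
  retained <- !is.na(d_mm) & s_out >= trim[1] & s_out <= L - trim[2]
  if (!any(retained)) stop("no cross-sections retained after end trimming")
  prof <- data.frame(s = s_out, d = d_mm, retained = retained)
  structure(prof,
            d_min = min(d_mm[retained]),
            d_average = mean(d_mm[retained]),
            artery_id = path$artery_id,
            n_dropped = n_drop,
            step_mm = config$step_mm,
            end_trim_mm = config$end_trim_mm,
            class = c("diameter_profile", "data.frame"))
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Build a diameter profile from raw diameters
#'
#' Convenience constructor used for direct arithmetic checks and for
#' profiles measured outside the straightening path.
#'
#' @param d numeric vector of diameters (mm), all positive.
#' @param s arclength positions (defaults to unit steps).
#' @param artery_id optional label.
#' @return a `diameter_profile`.
#' @export
diameter_profile <- function(d, s = seq_along(d) - 1, artery_id = NA_character_) {
  stopifnot(length(d) >= 1L, all(d > 0), length(s) == length(d))
  prof <- data.frame(s = s, d = d, retained = TRUE)
  structure(prof, d_min = min(d), d_average = mean(d), artery_id = artery_id,
            n_dropped = 0L, step_mm = if (length(s) > 1) diff(s)[1] else NA_real_,
            end_trim_mm = 0,
            class = c("diameter_profile", "data.frame"))
}

#' Stenosis score of a diameter profile
#'
#' The maximum-narrowing index `S = (1 - d_min / d_average) * 100` (percent),
#' where `d_min` and `d_average` are the minimum and mean diameters over the
#' retained cross-sections of the analyzed artery. Grades follow the
#' `< 50\%` / `>= 50\%` dichotomy (a score of exactly 50 is `>= 50%`).
#'
#' @param profile a `diameter_profile` (or a bare numeric vector of
#'   diameters, for arithmetic checks).
#' @return an object of class `stenosis_result`: `artery_id`, `S`, `grade`,
#'   `d_min`, `d_average`.
#' @export
compute_stenosis_score <- function(profile) {
  if (is.numeric(profile) && is.null(dim(profile))) profile <- diameter_profile(profile)
  stopifnot(inherits(profile, "diameter_profile"))
  n_ret <- sum(profile$retained)
  if (n_ret < 3L)
    stop("stenosis score undefined: fewer than 3 retained cross-sections")
  d_min <- attr(profile, "d_min")
  d_avg <- attr(profile, "d_average")
  S <- (1 - d_min / d_avg) * 100
  structure(list(artery_id = attr(profile, "artery_id"),
                 S = S,
                 grade = factor(if (S >= 50) ">=50%" else "<50%",
                                levels = c("<50%", ">=50%")),
                 d_min = d_min, d_average = d_avg, n_sections = n_ret),
            class = "stenosis_result")
}

#' @export
print.stenosis_result <- function(x, ...) {
  cat(sprintf("<stenosis_result> %s: S = %.2f%% (%s), d_min %.2f mm, d_average %.2f mm over %d sections\n",
              x$artery_id %||% "?", x$S, as.character(x$grade), x$d_min,
              x$d_average, x$n_sections))
  invisible(x)
}

#' Full pipeline configuration
#'
#' @param target_spacing_mm isotropic resampling target.
#' @param resample_order interpolation order for resampling.
#' @param segment a [segment_config()].
#' @param prune_mm skeleton spur-prune length.
#' @param straighten a [straighten_config()].
#' @param left_is_high_x laterality convention.
#' @param min_match_score artery-extraction acceptance threshold.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(target_spacing_mm = 0.5, resample_order = 1L,
                            segment = segment_config(),
                            prune_mm = 3,
                            straighten = straighten_config(),
                            left_is_high_x = TRUE,
                            min_match_score = 0.35) {
  structure(list(target_spacing_mm = target_spacing_mm,
                 resample_order = resample_order, segment = segment,
                 prune_mm = prune_mm, straighten = straighten,
                 left_is_high_x = left_is_high_x,
                 min_match_score = min_match_score),
            class = "pipeline_config")
}

run_vessel_stages <- function(volume, config) {
  vol_iso <- resample_isotropic(volume, config$target_spacing_mm,
                                order = config$resample_order)
  seg <- segment_vessels(vol_iso, config$segment)
  skel <- skeletonize_mask(seg, prune_mm = config$prune_mm)
  graph <- build_centerline_graph(skel)
  list(volume = vol_iso, segmentation = seg, skeleton = skel, graph = graph)
}

# Cross-sections taken within roughly one junction radius of a bifurcation
# cut through the junction blob and the sibling artery's lumen. Returns the
# per-end extra trim (mm): the local vessel radius (from the interior
# distance transform) at any junction node the path terminates on, else 0.
junction_end_trims <- function(path, graph, seg) {
  jn <- graph$nodes[graph$nodes$type == "junction", , drop = FALSE]
  if (nrow(jn) == 0L) return(c(0, 0))
  sp <- seg$spacing
  d <- dim(seg$mask)
  edt <- array(sqrt(cpp_edt_sq(as.logical(seg$mask), as.integer(d), sp)), dim = d)
  jxyz <- as.matrix(jn[, c("mm_x", "mm_y", "mm_z")])
  jrad <- vapply(seq_len(nrow(jn)), function(i) max(edt[jn$voxel[[i]]]), 0)
  vapply(c(1L, nrow(path$points)), function(i) {
    p <- path$points[i, ]
    dd <- sqrt(colSums((t(jxyz) - p)^2))
    j <- which.min(dd)
    if (dd[j] <= 2 * max(sp)) jrad[j] + max(sp) else 0
  }, 0)
}

#' Score the three posterior-circulation arteries of a volume
#'
#' Runs the full automated chain — isotropic resampling, threshold +
#' watershed segmentation, skeletonization, centerline graph, artery
#' localization, straightening and stenosis scoring — for the basilar
#' artery and both posterior cerebral arteries. One artery may fail
#' independently; its slot then carries the error message instead of a
#' result.
#'
#' @param volume a [vessel_volume()].
#' @param config a [pipeline_config()].
#' @return an object of class `stenosis_report`: `results` (named list of
#'   `stenosis_result` or `character` error per artery), `topology`,
#'   `provenance` (resolved parameters including the threshold used).
#' @export
score_posterior_circulation <- function(volume, config = pipeline_config()) {
  stages <- run_vessel_stages(volume, config)
  results <- list()
  for (aid in c("ba", "left_pca", "right_pca")) {
    results[[aid]] <- tryCatch({
      path <- extract_target_artery(stages$graph, aid,
                                    left_is_high_x = config$left_is_high_x,
                                    min_score = config$min_match_score)
      sc <- config$straighten
      sc$end_trim_mm <- sc$end_trim_mm[1] +
        junction_end_trims(path, stages$graph, stages$segmentation)
      prof <- straighten_artery(stages$segmentation, path, sc)
      compute_stenosis_score(prof)
    }, error = function(e) conditionMessage(e))
  }
  structure(list(results = results,
                 topology = graph_topology(stages$graph),
                 provenance = list(
                   threshold = stages$segmentation$threshold,
                   target_spacing_mm = config$target_spacing_mm,
                   prune_mm = config$prune_mm,
                   step_mm = config$straighten$step_mm,
                   end_trim_mm = config$straighten$end_trim_mm,
                   window_mm = config$straighten$window_mm,
                   left_is_high_x = config$left_is_high_x,
                   config_hash = config_hash(unclass_recursive(config)))),
            class = "stenosis_report")
}

#' Score a single-vessel volume
#'
#' Variant of [score_posterior_circulation()] for phantoms containing one
#' artery: the longest graph edge is taken as the vessel, bypassing the
#' anatomical priors.
#'
#' @inheritParams score_posterior_circulation
#' @return a `stenosis_result`.
#' @export
score_single_vessel <- function(volume, config = pipeline_config()) {
  stages <- run_vessel_stages(volume, config)
  if (length(stages$graph$edges) == 0L) stop("no vessel edge found in graph")
  lens <- vapply(stages$graph$edges, `[[`, 0, "length_mm")
  e <- stages$graph$edges[[which.max(lens)]]
  mm <- e$points_mm
  arc <- c(0, cumsum(sqrt(rowSums(diff(mm)^2))))
  path <- structure(list(artery_id = "vessel", points = mm, arclength = arc,
                         match_score = 1, diagnostics = NULL),
                    class = "artery_path")
  prof <- straighten_artery(stages$segmentation, path, config$straighten)
  compute_stenosis_score(prof)
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' @export
print.stenosis_report <- function(x, ...) {
  cat("<stenosis_report> topology:", paste(names(x$topology), x$topology,
                                           collapse = ", "), "\n")
  for (aid in names(x$results)) {
    r <- x$results[[aid]]
    if (inherits(r, "stenosis_result"))
      cat(sprintf("  %-10s S = %6.2f%%  (%s)\n", aid, r$S, as.character(r$grade)))
    else
      cat(sprintf("  %-10s FAILED: %s\n", aid, substr(r, 1, 60)))
  }
  invisible(x)
}
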