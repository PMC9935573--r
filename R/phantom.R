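#' Describe one synthetic artery
#'
#' An artery is a smooth space curve (natural cubic spline through the
#' control points) carrying a radius profile. Focal narrowings are Gaussian
#' dips in radius: at arclength `s` (mm),
#' `r(s) = base_radius * (1 - sum_k depth_k * exp(-(s - pos_k)^2 / (2 * width_k^2)))`,
#' where `pos_k` is the stenosis position as a fraction of total arclength.
#'
#' @param id artery identifier, e.g. `"ba"`, `"left_pca"`, `"right_pca"`.
#' @param control_points numeric matrix (n x 3) of mm coordinates.
#' @param base_radius lumen radius in mm away from any stenosis.
#' @param stenoses `NULL` or a data frame with columns `position` (arclength
#'   fraction in `[0,1]`), `depth` (fraction in `[0,1)`) and `width` (mm).
#' @return an object of class `artery_spec`.
#' @export
artery_spec <- function(id, control_points, base_radius, stenoses = NULL) {
  control_points <- as.matrix(control_points)
  if (ncol(control_points) != 3L || nrow(control_points) < 2L)
    stop("`control_points` must be an n x 3 matrix with n >= 2")
  stopifnot_scalar_positive(base_radius, "base_radius")
  if (!is.null(stenoses)) {
    stenoses <- as.data.frame(stenoses)
    stopifnot(all(c("position", "depth", "width") %in% names(stenoses)))
    if (any(stenoses$depth >= 1) || any(stenoses$depth < 0))
      stop("stenosis depth must lie in [0, 1): the lumen is never fully occluded")
    if (any(stenoses$position < 0) || any(stenoses$position > 1))
      stop("stenosis position must be an arclength fraction in [0, 1]")
    if (any(stenoses$width <= 0)) stop("stenosis width must be positive (mm)")
  }
  structure(list(id = id, control_points = control_points,
                 base_radius = base_radius, stenoses = stenoses),
            class = "artery_spec")
}

#' Specify a vessel phantom
#'
#' Bundles one or more arteries with the voxel grid they are rasterized
#' into and the imaging model (piecewise-constant intensity plus additive
#' Gaussian noise).
#'
#' @param arteries list of [artery_spec()] objects.
#' @param voxel_spacing mm triple.
#' @param volume_shape voxel triple.
#' @param foreground,background intensity inside / outside the lumen
#'   (arbitrary units).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed for the noise draw.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(arteries, voxel_spacing = c(0.6, 0.6, 0.6),
                         volume_shape = c(64, 64, 56),
                         foreground = 1000, background = 0,
                         noise_sd = 0, seed = 1L) {
  if (inherits(arteries, "artery_spec")) arteries <- list(arteries)
  stopifnot(length(arteries) >= 1L, all(vapply(arteries, inherits, TRUE, "artery_spec")))
  voxel_spacing <- as.numeric(voxel_spacing)
  volume_shape <- as.integer(volume_shape)
  stopifnot(length(voxel_spacing) == 3L, all(voxel_spacing > 0),
            length(volume_shape) == 3L, all(volume_shape >= 2L))
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  extent <- (volume_shape - 1L) * voxel_spacing
  for (a in arteries) {
    if (a$base_radius < 2 * max(voxel_spacing))
      stop(sprintf("artery '%s': base_radius (%.2f mm) must be at least twice the coarsest voxel spacing (%.2f mm) to be resolvable",
                   a$id, a$base_radius, max(voxel_spacing)))
    cp <- a$control_points
    if (any(cp < 0) || any(sweep(cp, 2, extent, ">")))
      stop(sprintf("artery '%s': control points fall outside the volume extent (%s mm)",
                   a$id, paste(signif(extent, 4), collapse = " x ")))
  }
  structure(list(arteries = arteries, voxel_spacing = voxel_spacing,
                 volume_shape = volume_shape, foreground = foreground,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Natural cubic spline through the control points, densified to n samples
# uniform in arclength. Returns list(points, s, length).
densify_centerline <- function(control_points, n) {
  cp <- control_points
  if (nrow(cp) == 2L) {
    t0 <- c(0, 1)
    fi <- function(tt, a) approx(t0, cp[, a], xout = tt)$y
  } else {
    ch <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
    t0 <- ch / max(ch)
    fi <- function(tt, a) spline(t0, cp[, a], xout = tt, method = "natural")$y
  }
  # first pass: uniform in parameter, then re-map to uniform arclength
  m <- max(4L * n, 256L)
  tt <- seq(0, 1, length.out = m)
  p0 <- cbind(fi(tt, 1), fi(tt, 2), fi(tt, 3))
  s0 <- c(0, cumsum(sqrt(rowSums(diff(p0)^2))))
  L <- s0[m]
  su <- seq(0, L, length.out = n)
  tu <- approx(s0, tt, xout = su, ties = "ordered")$y
  pts <- cbind(fi(tu, 1), fi(tu, 2), fi(tu, 3))
  list(points = pts, s = su, length = L)
}

# Radius profile r(s) of one artery evaluated at arclengths s (mm).
artery_radius <- function(artery, s, total_length) {
  r <- rep(artery$base_radius, length(s))
  st <- artery$stenoses
  if (!is.null(st) && nrow(st) > 0) {
    dip <- rep(0, length(s))
    for (k in seq_len(nrow(st)))
      dip <- dip + st$depth[k] * exp(-(s - st$position[k] * total_length)^2 / (2 * st$width[k]^2))
    r <- artery$base_radius * (1 - pmin(dip, 0.999))
  }
  r
}

#' Analytic stenosis score of a radius profile
#'
#' The score of a continuous radius function is
#' `(1 - min(r) / mean(r)) * 100`, evaluated here on a dense uniform
#' arclength grid; diameters and radii give the same ratio. It is 0 for a
#' constant profile and depends only on the continuous specification, never
#' on voxel spacing or noise.
#'
#' @param radii numeric vector of radius (or diameter) samples uniform in
#'   arclength.
#' @return score in `[0, 100)`.
#' @export
true_stenosis_score <- function(radii) {
  stopifnot(length(radii) >= 2L, all(radii > 0))
  (1 - min(radii) / mean(radii)) * 100
}

#' Generate a vessel phantom with ground truth
#'
#' Rasterizes each artery by the nearest-centerline rule (a voxel belongs to
#' the lumen iff its center lies within the radius attached to the nearest
#' point of the densely resampled centerline polyline, sampled at most a
#' quarter voxel apart, with exact point-to-segment distances so the axial
#' discretization adds no boundary bias). Voxels cut by the lumen wall get
#' the partial-volume intensity mixture `bg + (fg - bg) * fraction`, with
#' the fraction a linear ramp in the signed distance to the wall over one
#' mean voxel width — emulating the finite point-spread of MR acquisition,
#' whose edge voxels are intermediate in intensity, never knife-edged.
#' Seeded Gaussian noise is added last. The analytic truth — dense
#' centerline, radius profile and analytic stenosis score per artery — is
#' recorded alongside.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `phantom` with elements `volume`
#'   (a [vessel_volume()]) and `truth` (class `phantom_truth`: per artery the
#'   dense centerline in mm, arclength grid, radius samples, and `score`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$voxel_spacing
  shp <- spec$volume_shape
  n_vox <- prod(shp)
  margin <- rep(1e30, n_vox)  # signed distance to the nearest lumen wall
  n_truth <- 4097L  # fixed: the truth never depends on voxel spacing

  truth <- list()
  for (a in spec$arteries) {
    # densify so consecutive samples are <= 1/4 voxel apart
    probe <- densify_centerline(a$control_points, 256L)
    n_raster <- max(64L, as.integer(ceiling(probe$length / (min(sp) / 4))) + 1L)
    dc <- densify_centerline(a$control_points, n_raster)
    radii <- artery_radius(a, dc$s, dc$length)
    margin <- cpp_rasterize_tube(dc$points, radii, sp, as.integer(shp),
                                 max(radii) + max(sp), margin)
    tc <- densify_centerline(a$control_points, n_truth)
    tr <- artery_radius(a, tc$s, tc$length)
    truth[[a$id]] <- list(id = a$id, centerline = tc$points, s = tc$s,
                          radius = tr, length = tc$length,
                          score = true_stenosis_score(tr))
  }

  lumen <- margin <= 0
  frac <- pmin(1, pmax(0, 0.5 - margin / mean(sp)))  # partial-volume ramp
  intens <- array(spec$background + (spec$foreground - spec$background) * frac,
                  dim = shp)
  if (spec$noise_sd > 0) {
    noise <- local_seed(spec$seed, rnorm(n_vox, 0, spec$noise_sd))
    intens <- intens + array(noise, dim = shp)
  }

  structure(
    list(volume = vessel_volume(intens, spacing = sp),
         truth = structure(truth, class = "phantom_truth"),
         lumen = array(lumen, dim = shp),
         spec = spec),
    class = "phantom"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>\n")
  for (a in x)
    cat(sprintf("  %-10s length %6.1f mm  radius %.2f-%.2f mm  score %6.2f\n",
                a$id, a$length, min(a$radius), max(a$radius), a$score))
  invisible(x)
}

#' Default posterior-circulation phantom layout
#'
#' One basilar-artery trunk ascending at midline and bifurcating into the
#' two posterior cerebral arteries, which curve laterally and superiorly.
#' The arterial tree therefore has exactly one junction and three endpoints,
#' which fixes the topology oracle for the centerline graph. Under the
#' radiological display convention used throughout (subject-left on the
#' image-right), the left PCA occupies the high-x half of the grid.
#'
#' @param voxel_spacing,volume_shape grid geometry (defaults 0.6 mm, 64 x 64
#'   x 56 voxels).
#' @param ba_radius,pca_radius lumen radii in mm.
#' @param stenoses named list (names among `ba`, `left_pca`, `right_pca`) of
#'   stenosis data frames as in [artery_spec()].
#' @param mirror if `TRUE`, mirror the tree in x (swaps anatomical sides).
#' @param ... passed to [phantom_spec()] (`foreground`, `noise_sd`, `seed`, ...).
#' @return a [phantom_spec()].
#' @export
posterior_circulation_spec <- function(voxel_spacing = c(0.6, 0.6, 0.6),
                                       volume_shape = c(64, 64, 56),
                                       ba_radius = 2.0, pca_radius = 1.6,
                                       stenoses = list(), mirror = FALSE, ...) {
  extent <- (as.integer(volume_shape) - 1L) * voxel_spacing
  mx <- extent[1] / 2
  my <- extent[2] / 2
  zj <- extent[3] * 0.52                      # bifurcation height
  ba_pts <- rbind(c(mx, my, 3.0), c(mx, my, (3.0 + zj) / 2), c(mx, my, zj))
  lat <- c(3.2, 8.0, 12.0)                    # lateral excursion of the PCA
  up <- c(3.5, 8.0, 12.0)                     # superior excursion
  post <- c(1.2, 3.0, 4.5)                    # posterior drift
  l_pts <- rbind(c(mx, my, zj),
                 c(mx + lat[1], my + post[1], zj + up[1]),
                 c(mx + lat[2], my + post[2], zj + up[2]),
                 c(mx + lat[3], my + post[3], zj + up[3]))
  r_pts <- l_pts
  r_pts[, 1] <- 2 * mx - r_pts[, 1]
  if (mirror) {
    # mirror the geometry only; artery ids keep their construction names, so
    # the pipeline's anatomical labels are expected to swap sides
    for (p in c("ba_pts", "l_pts", "r_pts")) {
      v <- get(p)
      v[, 1] <- 2 * mx - v[, 1]
      assign(p, v)
    }
  }
  phantom_spec(
    arteries = list(
      artery_spec("ba", ba_pts, ba_radius, stenoses[["ba"]]),
      artery_spec("left_pca", l_pts, pca_radius, stenoses[["left_pca"]]),
      artery_spec("right_pca", r_pts, pca_radius, stenoses[["right_pca"]])
    ),
    voxel_spacing = voxel_spacing, volume_shape = volume_shape, ...
  )
}

#' Single straight-tube phantom
#'
#' A straight vessel along one grid axis, centered on a voxel line; the
#' workhorse geometry for convergence and recovery checks where the true
#' centerline and radius are known exactly.
#'
#' @param radius lumen radius (mm).
#' @param length tube length (mm).
#' @param spacing isotropic voxel spacing (mm).
#' @param axis `"x"`, `"y"` or `"z"`: tube direction.
#' @param stenoses stenosis data frame as in [artery_spec()].
#' @param ... passed to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
straight_tube_spec <- function(radius = 3, length = 30, spacing = 0.6,
                               axis = c("z", "x", "y"), stenoses = NULL, ...) {
  axis <- match.arg(axis)
  margin <- radius + 2.5
  lat_extent <- 2 * margin
  ax_extent <- length + 2 * margin
  sp <- rep(spacing, 3)
  n_lat <- as.integer(ceiling(lat_extent / spacing)) + 1L
  n_ax <- as.integer(ceiling(ax_extent / spacing)) + 1L
  # center the axis on an exact voxel line
  c_lat <- round((n_lat - 1) / 2) * spacing
  base_pts <- rbind(c(c_lat, c_lat, margin), c(c_lat, c_lat, margin + length))
  if (axis == "z") {
    pts <- base_pts; shape <- c(n_lat, n_lat, n_ax)
  } else if (axis == "x") {
    pts <- base_pts[, c(3, 1, 2), drop = FALSE]; shape <- c(n_ax, n_lat, n_lat)
  } else {
    pts <- base_pts[, c(1, 3, 2), drop = FALSE]; shape <- c(n_lat, n_ax, n_lat)
  }
  phantom_spec(arteries = artery_spec("tube", pts, radius, stenoses),
               voxel_spacing = sp, volume_shape = shape, ...)
}
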