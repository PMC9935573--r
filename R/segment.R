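#' Otsu threshold of an intensity sample
#'
#' Classic between-class variance maximization on a fixed-bin histogram,
#' used as the automatic global threshold for bright-vessel/dark-background
#' volumes. Returns the lower edge of the first background-free bin split.
#'
#' @param x numeric vector or array of intensities.
#' @param n_bins number of histogram bins.
#' @return a single threshold value; voxels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite intensities")
  rng <- range(x)
  if (diff(rng) == 0) stop("constant volume: no threshold separates foreground from background")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(x, br, all.inside = TRUE), 1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  sb <- (mu_t * w0 - mu)^2 / (w0 * w1)
  sb[!is.finite(sb)] <- -Inf
  sb <- sb[-n_bins]
  # the criterion plateaus across empty bins between well-separated classes;
  # take the plateau middle so the split bisects the gap
  ks <- which(sb >= max(sb) - 1e-10 * abs(max(sb)))
  k <- ks[ceiling(length(ks) / 2)]
  br[k + 1L]
}

#' Segmentation configuration
#'
#' @param threshold_mode `"otsu"` (automatic bimodal split), `"absolute"`, or
#'   `"percentile"` of the intensity distribution.
#' @param threshold_value absolute threshold or percentile in `[0,1]`,
#'   depending on the mode.
#' @param min_component_mm3 connected components smaller than this physical
#'   volume are discarded as noise.
#' @param watershed run marker-based watershed splitting of touching
#'   structures (markers = distance-transform local maxima).
#' @param marker_min_sep_mm minimum separation between watershed markers.
#' @return a list of class `segment_config`.
#' @export
segment_config <- function(threshold_mode = c("otsu", "absolute", "percentile"),
                           threshold_value = NULL,
                           min_component_mm3 = 2,
                           watershed = TRUE,
                           marker_min_sep_mm = 3) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode != "otsu" && is.null(threshold_value))
    stop("`threshold_value` is required for mode '", threshold_mode, "'")
  structure(list(threshold_mode = threshold_mode, threshold_value = threshold_value,
                 min_component_mm3 = min_component_mm3, watershed = watershed,
                 marker_min_sep_mm = marker_min_sep_mm),
            class = "segment_config")
}

#' Segment bright vascular structures
#'
#' Global thresholding (Otsu by default) followed by removal of small
#' components and marker-based watershed on the interior Euclidean distance
#' transform to split touching structures into instances. The binary mask is
#' the union of instances; instance labels and the resolved threshold are
#' kept as provenance.
#'
#' @param volume a [vessel_volume()] with finite intensities.
#' @param config a [segment_config()].
#' @return an object of class `segmentation_mask`: list with `mask` (logical
#'   array), `labels` (integer array of watershed instances), `spacing`,
#'   `threshold` and `provenance`.
#' @export
segment_vessels <- function(volume, config = segment_config()) {
  stopifnot(inherits(volume, "vessel_volume"), inherits(config, "segment_config"))
  x <- volume$intensities
  if (any(!is.finite(x))) stop("volume contains non-finite intensities")
  thr <- switch(config$threshold_mode,
    otsu = otsu_threshold(x),
    absolute = config$threshold_value,
    percentile = as.numeric(quantile(x, config$threshold_value))
  )
  d <- dim(x)
  sp <- volume$spacing
  mask <- as.logical(x > thr)
  if (!any(mask))
    stop("empty segmentation: no voxel exceeds the threshold (", signif(thr, 5), ")")

  lab <- cpp_label_components(mask, as.integer(d), 26L)
  sizes <- tabulate(lab[lab > 0L])
  vox_mm3 <- prod(sp)
  keep <- which(sizes * vox_mm3 >= config$min_component_mm3)
  n_removed <- length(sizes) - length(keep)
  mask <- mask & (lab %in% keep)
  if (!any(mask))
    stop("empty segmentation: all components fall below the ",
         config$min_component_mm3, " mm^3 size floor")

  labels <- array(as.integer(mask), dim = d)
  markers_n <- NA_integer_
  if (config$watershed) {
    edt <- sqrt(cpp_edt_sq(mask, as.integer(d), sp))
    cand <- which(cpp_local_maxima(edt, as.integer(d), mask))
    cand <- cand[order(edt[cand], decreasing = TRUE)]
    coords <- t(sapply(cand, function(i) ((arrayInd(i, d) - 1L) * sp)))
    sel <- integer(0)
    for (i in seq_along(cand)) {
      if (length(sel) == 0L) { sel <- i; next }
      dd <- sqrt(colSums((t(coords[sel, , drop = FALSE]) - coords[i, ])^2))
      if (all(dd >= config$marker_min_sep_mm)) sel <- c(sel, i)
    }
    marker_idx <- cand[sel]
    # guarantee at least one marker per connected component
    comp <- cpp_label_components(mask, as.integer(d), 26L)
    has_marker <- unique(comp[marker_idx])
    for (cc in setdiff(unique(comp[comp > 0L]), has_marker)) {
      in_cc <- which(comp == cc)
      marker_idx <- c(marker_idx, in_cc[which.max(edt[in_cc])])
    }
    markers <- integer(length(mask))
    markers[marker_idx] <- seq_along(marker_idx)
    labels <- array(cpp_watershed(mask, as.integer(d), edt, markers), dim = d)
    markers_n <- length(marker_idx)
  }

  structure(
    list(mask = array(mask, dim = d), labels = labels, spacing = sp,
         threshold = thr,
         provenance = list(threshold_mode = config$threshold_mode,
                           threshold = thr,
                           min_component_mm3 = config$min_component_mm3,
                           components_removed = n_removed,
                           watershed = config$watershed,
                           n_markers = markers_n)),
    class = "segmentation_mask"
  )
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat("<segmentation_mask> ", sum(x$mask), " foreground voxels (",
      signif(sum(x$mask) * prod(x$spacing), 4), " mm^3), threshold ",
      signif(x$threshold, 5), ", ", max(x$labels), " instance(s)\n", sep = "")
  invisible(x)
}

#' Dice overlap of two binary masks
#'
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
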