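#' Construct a vessel volume
#'
#' A `vessel_volume` is a 3D scalar intensity grid with physical voxel
#' spacing (mm) and an origin, the in-memory form of a TOF-MRA-like
#' acquisition in which flowing blood is bright on a dark background.
#'
#' @param intensities numeric 3D array.
#' @param spacing numeric length-3, mm per axis; strictly positive.
#' @param origin numeric length-3, mm position of the first voxel center.
#' @return an object of class `vessel_volume`.
#' @export
vessel_volume <- function(intensities, spacing, origin = c(0, 0, 0)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array")
  if (any(dim(intensities) < 1L)) stop("volume grid is empty")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers (mm)")
  structure(
    list(intensities = intensities, spacing = spacing, origin = as.numeric(origin)),
    class = "vessel_volume"
  )
}

#' @export
print.vessel_volume <- function(x, ...) {
  cat("<vessel_volume> ", paste(dim(x$intensities), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "), " mm\n",
      "  intensity range: [", signif(min(x$intensities), 5), ", ",
      signif(max(x$intensities), 5), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.vessel_volume <- function(x) dim(x$intensities)

#' Resample a volume onto an isotropic grid
#'
#' TOF-MRA acquisitions are typically anisotropic (slice thickness coarser
#' than in-plane resolution); isotropic resampling restores comparable
#' resolution along all axes before segmentation and skeletonization.
#' Physical extent is preserved to within one voxel.
#'
#' @param volume a [vessel_volume()].
#' @param target_spacing target isotropic spacing in mm.
#' @param order interpolation order: 0 (nearest neighbour) or 1 (trilinear).
#' @return a [vessel_volume()] with isotropic spacing.
#' @export
resample_isotropic <- function(volume, target_spacing, order = 1L) {
  stopifnot(inherits(volume, "vessel_volume"))
  stopifnot_scalar_positive(target_spacing, "target_spacing")
  if (!order %in% c(0L, 1L)) stop("`order` must be 0 or 1")
  sp <- volume$spacing
  if (target_spacing > 4 * max(sp))
    warning("target spacing is more than 4x coarser than the input; information will be lost")
  d_in <- dim(volume$intensities)
  if (all(abs(sp - target_spacing) < 1e-12)) return(volume)
  d_out <- pmax(1L, as.integer(floor((d_in - 1L) * sp / target_spacing + 1e-9)) + 1L)
  out <- cpp_resample(as.numeric(volume$intensities), as.integer(d_in), sp,
                      as.integer(d_out), target_spacing, as.integer(order))
  vessel_volume(array(out, dim = d_out), spacing = rep(target_spacing, 3),
                origin = volume$origin)
}

#' Read a NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file with spacing metadata.
#' @return a [vessel_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D volume, got ", length(d), " dimensions")
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0)) stop("volume is missing positive voxel spacing")
  sp <- signif(sp, 7)  # header stores float32; shed the representation noise
  arr <- array(as.numeric(img), dim = d)
  vessel_volume(arr, spacing = sp)
}

#' Write a volume as NIfTI
#'
#' @param volume a [vessel_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "vessel_volume"))
  img <- RNifti::asNifti(volume$intensities)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
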