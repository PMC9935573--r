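#' Write a phantom with its truth sidecar
#'
#' The volume goes to NIfTI (spacing in the header); the analytic truth —
#' centerlines (down-sampled to at most 257 points), radius samples and the
#' true stenosis score per artery — to a JSON sidecar.
#'
#' @param phantom a [generate_phantom()] result.
#' @param nii_path output `.nii` / `.nii.gz` path.
#' @param truth_path output `.json` path (default: `nii_path` with
#'   `_truth.json`).
#' @return named character vector of the two paths, invisibly.
#' @export
write_phantom <- function(phantom, nii_path, truth_path = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  truth_path <- truth_path %||% paste0(sub("\\.nii(\\.gz)?$", "", nii_path), "_truth.json")
  write_volume(phantom$volume, nii_path)
  thin <- function(a) {
    keep <- unique(round(seq(1, nrow(a$centerline), length.out = 257)))
    list(id = a$id, length_mm = a$length, score = a$score,
         centerline_mm = a$centerline[keep, , drop = FALSE],
         arclength_mm = a$s[keep], radius_mm = a$radius[keep])
  }
  jsonlite::write_json(lapply(unclass(phantom$truth), thin), truth_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(volume = nii_path, truth = truth_path))
}

#' Read a phantom truth sidecar
#'
#' @param truth_path path written by [write_phantom()].
#' @return list per artery with `score`, `centerline_mm`, `radius_mm`.
#' @export
read_phantom_truth <- function(truth_path) {
  jsonlite::read_json(truth_path, simplifyVector = TRUE)
}

#' Write stenosis results as JSON
#'
#' Serializes per-artery scores and grades together with the provenance
#' record, the seed and the resolved configuration hash, so any output
#' artifact identifies the run that produced it.
#'
#' @param report a [score_posterior_circulation()] result.
#' @param path output `.json` path.
#' @param seed the seed the run used (recorded verbatim).
#' @return `path`, invisibly.
#' @export
write_stenosis_results <- function(report, path, seed = NA_integer_) {
  stopifnot(inherits(report, "stenosis_report"))
  res <- lapply(report$results, function(r) {
    if (inherits(r, "stenosis_result"))
      list(S = r$S, grade = as.character(r$grade), d_min = r$d_min,
           d_average = r$d_average, n_sections = r$n_sections)
    else list(error = unclass(r))
  })
  payload <- list(results = res,
                  topology = as.list(report$topology),
                  provenance = report$provenance,
                  seed = seed)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
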