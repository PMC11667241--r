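#' Write / read a displacement field set
#'
#' The 5D array `(nx, ny, nz, 3, N)` goes to NIfTI; a JSON manifest
#' (`<path>.json`) records the convention (pull, `T(p) = p + D(p)`), the
#' units (voxels), the component order (x = fastest grid axis, then y, z),
#' the phase count and the grid spacing.
#'
#' @param dvfs displacement array `(nx, ny, nz, 3, N)` in voxel units.
#' @param path output NIfTI path.
#' @param spacing grid spacing (mm) recorded in the manifest.
#' @return `path` invisibly; `read_dvf_set` returns the array with the
#'   manifest attached as attribute `manifest`.
#' @export
write_dvf_set <- function(dvfs, path, spacing = c(1, 1, 1)) {
  RNifti::writeNifti(RNifti::asNifti(dvfs), path)
  manifest <- list(convention = "pull", units = "voxel",
                   component_order = c("x", "y", "z"),
                   n_phases = dim(dvfs)[5], spacing = spacing)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dvf_set
#' @export
read_dvf_set <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "manifest") <- jsonlite::read_json(paste0(path, ".json"),
                                               simplifyVector = TRUE)
  attr(arr, "units") <- "voxel"
  arr
}
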