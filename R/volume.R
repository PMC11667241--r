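#' 3D image volume container
#'
#' A light container for a 3D scalar image: a numeric array plus physical
#' spacing and origin. Voxel centers sit at `origin + (index - 1) * spacing`
#' (1-based indices); the world origin therefore lies half a voxel inside the
#' grid's bounding box corner. By default the grid is centered on the
#' isocenter (world coordinate 0,0,0).
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel spacing in mm (positive).
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   center, or `NULL` to center the grid on the isocenter.
#' @param semantics intensity meaning, `"attenuation"` (mm^-1) or
#'   `"normalized"` ([0,1]).
#' @return an object of class `cbct_volume`.
#' @export
cbct_volume <- function(data, spacing = c(1, 1, 1), origin = NULL,
                        semantics = c("attenuation", "normalized")) {
  semantics <- match.arg(semantics)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * spacing
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), semantics = semantics),
            class = "cbct_volume")
}

#' @export
print.cbct_volume <- function(x, ...) {
  cat("<cbct_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm (", x$semantics, ")\n", sep = "")
  cat("  origin (mm): ", paste(signif(x$origin, 5), collapse = ", "), "\n",
      sep = "")
  cat("  range: [", signif(min(x$data), 5), ", ", signif(max(x$data), 5),
      "]\n", sep = "")
  invisible(x)
}

#' @export
dim.cbct_volume <- function(x) dim(x$data)

is_cbct_volume <- function(x) inherits(x, "cbct_volume")

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes are not on the same grid (shape mismatch)")
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("volumes are not on the same grid (spacing mismatch)")
}

#' Voxel-center world coordinates of a grid
#'
#' @param vol a [cbct_volume()].
#' @return a list with vectors `x`, `y`, `z` of voxel-center coordinates (mm).
#' @export
voxel_coordinates <- function(vol) {
  d <- dim(vol$data)
  list(x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
       y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
       z = vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3])
}

#' Write / read a volume as NIfTI
#'
#' Volumes are stored with their spacing in the NIfTI header; displacement
#' field sets (5D arrays `x,y,z,component,phase`) are written the same way.
#'
#' @param vol a [cbct_volume()] (or a plain array for `write_nifti_array`).
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly; `read_volume` returns a [cbct_volume()].
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param spacing,origin,semantics grid metadata for the returned volume;
#'   spacing defaults to the NIfTI header pixdim.
#' @export
read_volume <- function(path, spacing = NULL, origin = NULL,
                        semantics = "attenuation") {
  img <- RNifti::readNifti(path)
  if (is.null(spacing)) spacing <- RNifti::pixdim(img)[1:3]
  cbct_volume(array(as.numeric(img), dim = dim(img)), spacing = spacing,
              origin = origin, semantics = semantics)
}

#' Percentile-clip intensity normalization
#'
#' Clips values to the 0.5 and 99.5 percentiles of the volume's own intensity
#' distribution and maps the clipped range affinely to `[0, 1]`. The affine
#' parameters are attached so the mapping can be inverted exactly on clipped
#' values.
#'
#' @param vol a [cbct_volume()].
#' @param probs lower/upper clipping percentiles (fractions).
#' @return a normalized [cbct_volume()] with attribute `affine`
#'   (`list(scale, shift)` such that `normalized = (clipped - shift) * scale`).
#' @export
normalize_intensity <- function(vol, probs = c(0.005, 0.995)) {
  q <- stats::quantile(vol$data, probs = probs, names = FALSE, type = 7)
  if (diff(q) <= 0) {
    warning("constant volume: normalization is degenerate, returning zeros")
    out <- cbct_volume(array(0, dim(vol$data)), vol$spacing, vol$origin,
                       "normalized")
    attr(out, "affine") <- list(scale = 0, shift = q[1])
    return(out)
  }
  x <- pmin(pmax(vol$data, q[1]), q[2])
  scale <- 1 / (q[2] - q[1])
  out <- cbct_volume((x - q[1]) * scale, vol$spacing, vol$origin, "normalized")
  attr(out, "affine") <- list(scale = scale, shift = q[1])
  out
}

#' Invert [normalize_intensity()]
#'
#' @param vol a normalized volume carrying the `affine` attribute (or pass
#'   `affine` explicitly).
#' @param affine the `list(scale, shift)` returned by the normalization.
#' @return a [cbct_volume()] back on the clipped attenuation scale.
#' @export
denormalize_intensity <- function(vol, affine = attr(vol, "affine")) {
  if (is.null(affine)) stop("no affine parameters available for inversion")
  if (affine$scale == 0) return(cbct_volume(array(affine$shift, dim(vol$data)),
                                            vol$spacing, vol$origin))
  cbct_volume(vol$data / affine$scale + affine$shift, vol$spacing, vol$origin)
}
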