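#' Circular full-fan cone-beam geometry
#'
#' Describes a single circular source/flat-detector trajectory. Angles are in
#' radians, counter-clockwise about the z axis; at angle 0 the source sits at
#' `(0, +SID, 0)` and the detector is centered on the central ray at distance
#' SDD from the source, with its u axis in the rotation plane and v along +z.
#' Only full-fan (centered detector) scans are supported; half-fan
#' (displaced-detector) acquisitions are rejected wherever geometry is
#' consumed.
#'
#' @param sid source-to-isocenter distance (mm).
#' @param sdd source-to-detector distance (mm), `> sid`.
#' @param nu,nv detector size in pixels (u = lateral, v = axial).
#' @param du,dv detector pixel spacing (mm).
#' @param full_fan logical; must be `TRUE`.
#' @return an object of class `cone_beam_geometry`.
#' @export
cone_beam_geometry <- function(sid = 1000, sdd = 1500, nu = 128, nv = 96,
                               du = 3.5, dv = 3.5, full_fan = TRUE) {
  if (!(sdd > sid && sid > 0)) stop("require SDD > SID > 0")
  if (!full_fan) stop("half-fan geometry is unsupported")
  structure(list(sid = sid, sdd = sdd, nu = as.integer(nu),
                 nv = as.integer(nv), du = du, dv = dv, full_fan = TRUE),
            class = "cone_beam_geometry")
}

#' @export
print.cone_beam_geometry <- function(x, ...) {
  cat("<cone_beam_geometry> SID", x$sid, "mm, SDD", x$sdd, "mm, detector",
      x$nu, "x", x$nv, "px @", x$du, "x", x$dv, "mm, full-fan\n")
  invisible(x)
}

#' Cone-beam projection stack
#'
#' A stack of 2D line-integral projections with per-projection gantry angle
#' and acquisition timestamp.
#'
#' @param data numeric array `(nu, nv, n_projections)` of line integrals
#'   (unitless).
#' @param angles gantry angles in radians, one per projection.
#' @param times acquisition timestamps in seconds, one per projection.
#' @param geometry a [cone_beam_geometry()].
#' @return an object of class `projection_set`.
#' @export
projection_set <- function(data, angles, times, geometry) {
  d <- dim(data)
  if (length(d) != 3L) stop("projection data must be a 3D array (u, v, proj)")
  if (d[1] != geometry$nu || d[2] != geometry$nv)
    stop("projection array shape inconsistent with detector geometry")
  if (length(angles) != d[3] || length(times) != d[3])
    stop("angles/times length must match the number of projections")
  if (!all(is.finite(data))) stop("projections contain non-finite values")
  structure(list(data = data, angles = as.numeric(angles),
                 times = as.numeric(times), geometry = geometry),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat("<projection_set>", dim(x$data)[3], "projections,",
      dim(x$data)[1], "x", dim(x$data)[2], "px, arc",
      signif(diff(range(x$angles)) * 180 / pi, 4), "deg over",
      signif(diff(range(x$times)), 4), "s\n")
  invisible(x)
}

n_projections <- function(p) dim(p$data)[3]

#' Write / read projections with a JSON geometry sidecar
#'
#' The projection stack goes to NIfTI; SID/SDD, pixel spacing, angles and
#' timestamps go to `<path>.json`.
#'
#' @param projections a [projection_set()].
#' @param path base output path for the NIfTI file.
#' @return `path` invisibly; `read_projections` returns a [projection_set()].
#' @export
write_projections <- function(projections, path) {
  g <- projections$geometry
  RNifti::writeNifti(RNifti::asNifti(projections$data), path)
  side <- list(sid = g$sid, sdd = g$sdd, nu = g$nu, nv = g$nv, du = g$du,
               dv = g$dv, full_fan = g$full_fan,
               angles = projections$angles, times = projections$times)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- cone_beam_geometry(side$sid, side$sdd, side$nu, side$nv,
                             side$du, side$dv, side$full_fan)
  projection_set(array(as.numeric(img), dim = dim(img)), side$angles,
                 side$times, geom)
}

#' Grid specification helper
#'
#' @param dims integer length-3 voxel counts.
#' @param spacing numeric length-3 spacing in mm.
#' @param origin optional world position of the first voxel center (mm);
#'   `NULL` centers the grid on the isocenter.
#' @return a list used by the reconstruction routines.
#' @export
grid_spec <- function(dims = c(64, 64, 48), spacing = c(4, 4, 4),
                      origin = NULL) {
  dims <- as.integer(dims)
  if (is.null(origin)) origin <- -(dims - 1) / 2 * spacing
  list(dims = dims, spacing = as.numeric(spacing), origin = as.numeric(origin))
}

empty_volume <- function(grid, semantics = "attenuation") {
  cbct_volume(array(0, grid$dims), grid$spacing, grid$origin, semantics)
}
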