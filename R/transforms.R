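# sample each component of a displacement field at p + offset(p)
sample_field <- function(dvf, offset) {
  d <- dim(dvf)[1:3]
  out <- dvf
  for (c in 1:3)
    out[, , , c] <- cpp_warp(dvf[, , , c], d, offset, FALSE)$value
  out
}

#' Invert a displacement field
#'
#' Fixed-point inversion of the transform `T(p) = p + D(p)`: iterates
#' `D_inv(p) <- -D(p + D_inv(p))` from zero until the maximum update falls
#' below `tol` (voxels) or the iteration cap is reached. Divergence (the
#' update growing for five consecutive iterations) raises an error.
#'
#' @param dvf displacement array `(nx, ny, nz, 3)` in voxel units.
#' @param tol stopping threshold on the maximum update (voxels).
#' @param max_iter iteration cap.
#' @return the inverse displacement field, same shape and units.
#' @export
invert_transform <- function(dvf, tol = 0.01, max_iter = 50) {
  inv <- array(0, dim(dvf))
  prev <- Inf
  growing <- 0
  for (it in seq_len(max_iter)) {
    nxt <- -sample_field(dvf, inv)
    upd <- max(abs(nxt - inv))
    inv <- nxt
    if (upd < tol) return(inv)
    growing <- if (upd > prev) growing + 1 else 0
    if (growing >= 5)
      stop(sprintf("displacement inversion diverging (update %.3g voxels)", upd))
    prev <- upd
  }
  inv
}

#' Compose two displacement fields
#'
#' Realizes `T_c = T_a o T_b` for pull-convention transforms
#' `T(p) = p + D(p)`: `D_c(p) = D_b(p) + D_a(p + D_b(p))`, with trilinear
#' sampling of `D_a`.
#'
#' @param dvf_a,dvf_b displacement arrays `(nx, ny, nz, 3)` in voxel units
#'   on the same grid.
#' @return the composed displacement field.
#' @export
compose_transforms <- function(dvf_a, dvf_b) {
  if (!identical(dim(dvf_a), dim(dvf_b))) stop("field shape mismatch")
  dvf_b + sample_field(dvf_a, dvf_b)
}

#' Inter-phase motion model from phase-to-template displacements
#'
#' For every ordered phase pair (i, j) the inter-phase transform is the
#' composition of the template-to-phase-j transform with the inverse of the
#' template-to-phase-i transform: `D_i^j = compose(D_tem^j,
#' invert(D_tem^i))`, realizing `I_i = I_j o T_i^j`. The inverses are
#' precomputed; pair fields are composed on demand by [motion_field()]
#' (the diagonal is exactly zero).
#'
#' @param dvfs array `(nx, ny, nz, 3, N)` of phase-to-template
#'   displacements in voxel units (the registration output).
#' @param tol,max_iter passed to [invert_transform()].
#' @return an object of class `motion_model`.
#' @export
build_motion_model <- function(dvfs, tol = 0.01, max_iter = 50) {
  N <- dim(dvfs)[5]
  inv <- array(0, dim(dvfs))
  for (i in seq_len(N))
    inv[, , , , i] <- invert_transform(dvfs[, , , , i], tol, max_iter)
  structure(list(n = N, tem = dvfs, inv = inv,
                 dims = dim(dvfs)[1:3], source = "registration"),
            class = "motion_model")
}

#' Motion model directly from known inter-phase fields
#'
#' Used for ground-truth motion models where every pair field is available
#' analytically (see [ground_truth_motion_model()]).
#'
#' @param pair_fun function `(i, j)` returning the voxel-unit displacement
#'   array mapping phase-i voxels into phase j (pull convention).
#' @param n number of phases.
#' @param dims grid dims.
#' @return an object of class `motion_model`.
#' @export
motion_model_from_pairs <- function(pair_fun, n, dims) {
  structure(list(n = n, pair_fun = pair_fun, dims = dims, source = "pairs"),
            class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  cat("<motion_model>", x$n, "phases on",
      paste(x$dims, collapse = " x "), "grid (", x$source, ")\n")
  invisible(x)
}

#' Inter-phase displacement field of a motion model
#'
#' @param model a motion model.
#' @param i,j 1-based phase indices; the returned field maps phase-i voxels
#'   to their phase-j positions (pull convention, voxel units).
#' @return displacement array `(nx, ny, nz, 3)`.
#' @export
motion_field <- function(model, i, j) {
  if (i < 1 || i > model$n || j < 1 || j > model$n)
    stop(sprintf("phase index out of range (n = %d)", model$n))
  if (i == j) return(array(0, c(model$dims, 3)))
  if (model$source == "pairs") return(model$pair_fun(i, j))
  compose_transforms(model$tem[, , , , j], model$inv[, , , , i])
}

#' Identity motion model
#'
#' All pair fields are zero; motion-compensated reconstruction with this
#' model reduces exactly to standard FDK.
#'
#' @param n number of phases.
#' @param dims grid dims.
#' @return a `motion_model`.
#' @export
identity_motion_model <- function(n, dims) {
  motion_model_from_pairs(function(i, j) array(0, c(dims, 3)), n, dims)
}

#' Ground-truth motion model of the breathing phantom
#'
#' Analytic inter-phase fields from the phantom's Lagrangian motion,
#' converted to voxel units on the reconstruction grid. Phase b of N covers
#' fraction `b / N` (bin centers, consistent with peak-centered binning).
#'
#' @inheritParams rasterize_phantom
#' @param n_phases number of phases N.
#' @return a `motion_model`.
#' @export
ground_truth_motion_model <- function(spec, breathing, n_phases, grid) {
  fractions <- (seq_len(n_phases) - 1) / n_phases
  pair_fun <- function(i, j) {
    d <- ground_truth_dvf(spec, breathing, fractions[i], fractions[j], grid)
    dvf_mm_to_voxel(d, grid$spacing)
  }
  motion_model_from_pairs(pair_fun, n_phases, grid$dims)
}
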