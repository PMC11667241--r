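#' Motion-compensated FDK reconstruction of one target phase
#'
#' Backprojects every projection (not just the target phase's bin) into the
#' target-phase grid along warped trajectories: for a projection acquired in
#' phase j, each voxel p of the target phase i is first displaced to
#' `p' = p + D_i^j(p)` (the motion model's pull-convention field) before its
#' detector coordinates and FDK distance weight are computed. Filtering
#' (cosine weight + ramp) is identical to standard FDK; with an identity
#' motion model the result is bit-for-bit the all-projection FDK volume.
#'
#' @param projections a [projection_set()].
#' @param binning a phase [phase_bin()] result labeling every projection.
#' @param motion_model a [build_motion_model()],
#'   [ground_truth_motion_model()] or [identity_motion_model()] with as many
#'   phases as `binning` has bins.
#' @param target_bin 0-based target phase bin.
#' @param grid a [grid_spec()].
#' @param window ramp apodization.
#' @return a [cbct_volume()].
#' @export
moco_reconstruct <- function(projections, binning, motion_model, target_bin,
                             grid = grid_spec(), window = "ram-lak") {
  g <- projections$geometry
  if (!isTRUE(g$full_fan)) stop("half-fan geometry is unsupported")
  N <- binning$n_bins
  if (motion_model$n != N)
    stop("motion model phase count does not match the binning")
  if (target_bin < 0 || target_bin >= N) stop("target phase out of range")
  if (!identical(as.integer(motion_model$dims), as.integer(grid$dims)))
    stop("motion model grid does not match the reconstruction grid")
  filtered <- fdk_filter(projections, window)
  w <- angular_weights(projections$angles)
  disp <- array(0, c(grid$dims, 3, N))
  for (j in seq_len(N))
    disp[, , , , j] <- motion_field(motion_model, target_bin + 1L, j)
  vol <- cpp_backproject_moco(filtered$data, dim(filtered$data),
                              projections$angles, w, binning$bin,
                              grid$dims, grid$spacing, grid$origin,
                              g$sid, g$sdd, g$du, g$dv, disp, N)
  cbct_volume(vol, grid$spacing, grid$origin)
}

#' Motion-compensated 4D reconstruction (all phases)
#'
#' Runs [moco_reconstruct()] for every target phase; each projection
#' contributes to every target phase exactly once.
#'
#' @inheritParams moco_reconstruct
#' @return a [phase_image_set()] of `n_bins` volumes.
#' @export
moco_reconstruct_4d <- function(projections, binning, motion_model,
                                grid = grid_spec(), window = "ram-lak") {
  vols <- lapply(seq_len(binning$n_bins) - 1L, function(b)
    moco_reconstruct(projections, binning, motion_model, b, grid, window))
  phase_image_set(vols)
}
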