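#' Deformable digital thorax phantom
#'
#' Defines a simple analytic thorax: a body ellipsoid, two lung ellipsoids
#' truncated inferiorly by a diaphragm dome, a tumor sphere, vessel cylinders
#' and rib-like high-attenuation shells. All geometry is in world mm with the
#' isocenter at the origin; attenuation is in mm^-1. The analytic form keeps
#' chord lengths, centroids and deformations exactly computable, which the
#' test oracles rely on.
#'
#' @param body_center,body_semiaxes body ellipsoid (mm).
#' @param mu_body,mu_lung,mu_tumor,mu_bone,mu_vessel attenuations (mm^-1);
#'   must satisfy `mu_lung < mu_body < mu_bone` and all be non-negative.
#' @param lung_centers,lung_semiaxes two lung ellipsoids (list of centers /
#'   shared semi-axes, mm).
#' @param tumor_center,tumor_radius tumor sphere (mm); should lie inside a
#'   lung.
#' @param diaphragm_apex_z apex of the diaphragm dome (mm); lung tissue
#'   exists only above the dome surface.
#' @param diaphragm_curvature dome droop per squared lateral distance
#'   (mm^-1).
#' @param vessels list of cylinders, each `list(center_xy, radius, z_range)`.
#' @param rib_scale rib-cage shell as a fraction band of the body ellipsoid.
#' @param rib_z_bands list of z intervals (mm) carrying the bony shell.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_center = c(0, 0, 0),
                         body_semiaxes = c(120, 90, 92),
                         mu_body = 0.02, mu_lung = 0.005, mu_tumor = 0.024,
                         mu_bone = 0.04, mu_vessel = 0.022,
                         lung_centers = list(c(-55, 0, 20), c(55, 0, 20)),
                         lung_semiaxes = c(42, 55, 68),
                         tumor_center = c(55, 5, 30), tumor_radius = 12,
                         diaphragm_apex_z = -30, diaphragm_curvature = 0.004,
                         vessels = list(list(center_xy = c(-40, 0), radius = 4,
                                             z_range = c(-20, 60)),
                                        list(center_xy = c(40, -5), radius = 4,
                                             z_range = c(-20, 60))),
                         rib_scale = c(0.90, 0.98),
                         rib_z_bands = list(c(-10, 5), c(25, 40), c(60, 75))) {
  mus <- c(mu_body, mu_lung, mu_tumor, mu_bone, mu_vessel)
  if (any(mus < 0)) stop("attenuations must be non-negative")
  if (!(mu_lung <= mu_body && mu_body <= mu_bone))
    stop("require mu_lung <= mu_body <= mu_bone")
  structure(list(body_center = body_center, body_semiaxes = body_semiaxes,
                 mu_body = mu_body, mu_lung = mu_lung, mu_tumor = mu_tumor,
                 mu_bone = mu_bone, mu_vessel = mu_vessel,
                 lung_centers = lung_centers, lung_semiaxes = lung_semiaxes,
                 tumor_center = tumor_center, tumor_radius = tumor_radius,
                 diaphragm_apex_z = diaphragm_apex_z,
                 diaphragm_curvature = diaphragm_curvature,
                 vessels = vessels, rib_scale = rib_scale,
                 rib_z_bands = rib_z_bands),
            class = "phantom_spec")
}

# squared normalized ellipsoid coordinate (1 on the surface)
ellipsoid_rho2 <- function(pts, center, semi) {
  ((pts[, 1] - center[1]) / semi[1])^2 +
    ((pts[, 2] - center[2]) / semi[2])^2 +
    ((pts[, 3] - center[3]) / semi[3])^2
}

# diaphragm dome height under a lung at lateral position (x, y)
dome_z <- function(spec, pts, lung_center) {
  spec$diaphragm_apex_z - spec$diaphragm_curvature *
    ((pts[, 1] - lung_center[1])^2 + (pts[, 2] - lung_center[2])^2)
}

phantom_lung_membership <- function(spec, pts) {
  inside <- rep(FALSE, nrow(pts))
  for (lc in spec$lung_centers) {
    in_l <- ellipsoid_rho2(pts, lc, spec$lung_semiaxes) <= 1 &
      pts[, 3] > dome_z(spec, pts, lc)
    inside <- inside | in_l
  }
  inside
}

#' Evaluate the phantom attenuation at world points (reference state)
#'
#' @param spec a [phantom_spec()].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return attenuation values (mm^-1), length n.
#' @export
evaluate_phantom <- function(spec, pts) {
  pts <- matrix(pts, ncol = 3)
  att <- numeric(nrow(pts))
  rho2_body <- ellipsoid_rho2(pts, spec$body_center, spec$body_semiaxes)
  in_body <- rho2_body <= 1
  att[in_body] <- spec$mu_body
  # rib-like shell: band of the body ellipsoid within selected z intervals
  shell <- rho2_body >= spec$rib_scale[1]^2 & rho2_body <= spec$rib_scale[2]^2
  in_band <- rep(FALSE, nrow(pts))
  for (b in spec$rib_z_bands) in_band <- in_band | (pts[, 3] >= b[1] & pts[, 3] <= b[2])
  att[shell & in_band] <- spec$mu_bone
  # lungs above the diaphragm dome
  att[phantom_lung_membership(spec, pts)] <- spec$mu_lung
  # vessels inside the lungs
  for (v in spec$vessels) {
    in_v <- (pts[, 1] - v$center_xy[1])^2 + (pts[, 2] - v$center_xy[2])^2 <=
      v$radius^2 & pts[, 3] >= v$z_range[1] & pts[, 3] <= v$z_range[2] &
      phantom_lung_membership(spec, pts)
    att[in_v] <- spec$mu_vessel
  }
  # tumor
  in_t <- rowSums(sweep(pts, 2, spec$tumor_center)^2) <= spec$tumor_radius^2
  att[in_t] <- spec$mu_tumor
  att
}

#' Breathing motion model
#'
#' One-parameter respiratory surrogate: the phase-fraction-to-amplitude
#' function is `a(phi) = sin^2(pi * phi)` (0 at the resting end-exhale state
#' `phi = 0`, single inhale peak at `phi = 0.5`), and the spatial weight field
#' `u(p)` is superior-inferior dominant with a cosine-squared falloff from the
#' diaphragm apex to the lung apex, a 20% anterior-posterior component, and a
#' smoothstep taper to zero at the body surface. `||u|| = 1` at the diaphragm
#' apex, so `amplitude` is the peak diaphragm excursion in mm. The field is
#' continuously differentiable, which keeps fixed-point pull-backs and
#' composed/inverted fields accurate.
#'
#' @param spec a [phantom_spec()] providing the body/lung geometry the weight
#'   field is anchored to.
#' @param amplitude peak superior-inferior diaphragm excursion A (mm).
#' @param period breathing period (s).
#' @param ap_fraction anterior-posterior motion as a fraction of
#'   superior-inferior motion.
#' @param body_taper width (in normalized ellipsoid coordinate) of the taper
#'   band inside the body surface over which motion falls to zero.
#' @return an object of class `breathing_model`.
#' @export
breathing_model <- function(spec, amplitude = 10, period = 4,
                            ap_fraction = 0.2, body_taper = 0.43) {
  lung_top <- max(vapply(spec$lung_centers, function(c) c[3], 0)) +
    spec$lung_semiaxes[3]
  structure(list(spec = spec, amplitude = amplitude, period = period,
                 ap_fraction = ap_fraction, body_taper = body_taper,
                 z_dia = spec$diaphragm_apex_z, z_apex = lung_top),
            class = "breathing_model")
}

#' @rdname breathing_model
#' @param phase_fraction respiratory phase fraction(s) in `[0, 1)`.
#' @return `phase_amplitude`: the unitless amplitude `a(phi)` in `[0, 1]`.
#' @export
phase_amplitude <- function(breathing, phase_fraction) {
  sin(pi * phase_fraction)^2
}

#' @rdname breathing_model
#' @param breathing a `breathing_model`.
#' @param pts n x 3 matrix of world points (mm).
#' @return `motion_weight`: n x 3 matrix of unitless direction weights
#'   `u(p)`; zero outside the body.
#' @export
motion_weight <- function(breathing, pts) {
  pts <- matrix(pts, ncol = 3)
  spec <- breathing$spec
  t <- (pts[, 3] - breathing$z_dia) / (breathing$z_apex - breathing$z_dia)
  w <- ifelse(t <= 0, 1, ifelse(t >= 1, 0, cos(pi / 2 * t)^2))
  rho <- sqrt(ellipsoid_rho2(pts, spec$body_center, spec$body_semiaxes))
  s <- pmin(1, pmax(0, (1 - rho) / breathing$body_taper))
  chi <- s * s * (3 - 2 * s)          # smoothstep: C1 taper to the surface
  dir <- c(0, breathing$ap_fraction, -1)
  dir <- dir / sqrt(sum(dir^2))
  mag <- w * chi
  cbind(dir[1] * mag, dir[2] * mag, dir[3] * mag)
}

# Lagrangian forward motion: reference point -> position at phase phi
deform_points <- function(breathing, pts, phase_fraction) {
  a <- phase_amplitude(breathing, phase_fraction)
  matrix(pts, ncol = 3) + a * breathing$amplitude * motion_weight(breathing, pts)
}

# Eulerian pull-back: grid point p at phase phi -> reference point x with
# x + a A u(x) = p, solved by fixed-point iteration.
pullback_points <- function(breathing, pts, phase_fraction, tol = 1e-4,
                            max_iter = 100) {
  pts <- matrix(pts, ncol = 3)
  a <- phase_amplitude(breathing, phase_fraction)
  if (a * breathing$amplitude == 0) return(pts)
  x <- pts
  for (it in seq_len(max_iter)) {
    xn <- pts - a * breathing$amplitude * motion_weight(breathing, x)
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < tol) return(x)
  }
  stop(sprintf(
    "pull-back fixed point did not converge: worst residual %.3g mm", delta))
}

#' Rasterize the breathing phantom at a respiratory phase
#'
#' Voxelizes the analytic phantom at the Eulerian positions of phase
#' `phase_fraction`: material at reference point x appears at
#' `x + a(phi) * A * u(x)`. The pull-back is solved per voxel by fixed-point
#' iteration and the analytic phantom evaluated at the recovered reference
#' point, so interfaces stay sharp at any phase.
#'
#' @param spec a [phantom_spec()].
#' @param breathing a [breathing_model()].
#' @param phase_fraction phase in `[0, 1)`.
#' @param grid a [grid_spec()].
#' @return a [cbct_volume()] of attenuation (mm^-1).
#' @export
rasterize_phantom <- function(spec, breathing, phase_fraction, grid) {
  if (phase_fraction < 0 || phase_fraction >= 1)
    stop("phase_fraction must lie in [0, 1)")
  extent_lo <- grid$origin - grid$spacing / 2
  extent_hi <- grid$origin + (grid$dims - 0.5) * grid$spacing
  lo <- spec$body_center - spec$body_semiaxes
  hi <- spec$body_center + spec$body_semiaxes
  if (any(lo < extent_lo) || any(hi > extent_hi))
    warning("phantom extends outside the grid; structures are clipped")
  co <- list(x = grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$spacing[1],
             y = grid$origin[2] + (seq_len(grid$dims[2]) - 1) * grid$spacing[2],
             z = grid$origin[3] + (seq_len(grid$dims[3]) - 1) * grid$spacing[3])
  pts <- as.matrix(expand.grid(x = co$x, y = co$y, z = co$z))
  ref <- pullback_points(breathing, pts, phase_fraction)
  att <- evaluate_phantom(spec, ref)
  cbct_volume(array(att, grid$dims), grid$spacing, grid$origin)
}

#' Ground-truth inter-phase displacement field
#'
#' Pull-convention field on the phase-i grid: for voxel center p (phase i),
#' the returned displacement d satisfies "the same material point sits at
#' p + d in phase j". Computed by solving the Lagrangian motion for the
#' reference point by fixed-point iteration, then pushing it forward to
#' phase j. Units are mm (world); see [dvf_mm_to_voxel()] for the voxel-unit
#' convention used by the registration module.
#'
#' @inheritParams rasterize_phantom
#' @param phase_i,phase_j phases in `[0, 1)`.
#' @return array `(nx, ny, nz, 3)` of mm displacements, with attributes
#'   `spacing` and `origin`.
#' @export
ground_truth_dvf <- function(spec, breathing, phase_i, phase_j, grid) {
  if (any(c(phase_i, phase_j) < 0) || any(c(phase_i, phase_j) >= 1))
    stop("phases must lie in [0, 1)")
  if (phase_amplitude(breathing, phase_i) ==
        phase_amplitude(breathing, phase_j)) {
    out <- array(0, c(grid$dims, 3))
    attr(out, "spacing") <- grid$spacing
    attr(out, "origin") <- grid$origin
    attr(out, "units") <- "mm"
    return(out)
  }
  co <- list(x = grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$spacing[1],
             y = grid$origin[2] + (seq_len(grid$dims[2]) - 1) * grid$spacing[2],
             z = grid$origin[3] + (seq_len(grid$dims[3]) - 1) * grid$spacing[3])
  pts <- as.matrix(expand.grid(x = co$x, y = co$y, z = co$z))
  ref <- pullback_points(breathing, pts, phase_i)
  yj <- deform_points(breathing, ref, phase_j)
  d <- yj - pts
  out <- array(d, c(grid$dims, 3))
  attr(out, "spacing") <- grid$spacing
  attr(out, "origin") <- grid$origin
  attr(out, "units") <- "mm"
  out
}

#' Convert a mm displacement field to voxel units (and back)
#'
#' @param dvf array `(nx, ny, nz, 3)`.
#' @param spacing voxel spacing (mm).
#' @return the converted field.
#' @export
dvf_mm_to_voxel <- function(dvf, spacing = attr(dvf, "spacing")) {
  d <- dim(dvf)
  out <- dvf
  for (c in 1:3) out[, , , c] <- dvf[, , , c] / spacing[c]
  attr(out, "units") <- "voxel"
  out
}

#' @rdname dvf_mm_to_voxel
#' @export
dvf_voxel_to_mm <- function(dvf, spacing) {
  d <- dim(dvf)
  out <- dvf
  for (c in 1:3) out[, , , c] <- dvf[, , , c] * spacing[c]
  attr(out, "units") <- "mm"
  out
}

#' Paired ground-truth landmarks inside the lungs
#'
#' Samples reference points uniformly inside the lung regions (within the
#' grid extent) and maps them through the Lagrangian motion to phases i and
#' j, producing exactly corresponding pairs.
#'
#' @inheritParams ground_truth_dvf
#' @param n_points number of landmark pairs.
#' @param seed RNG seed (sampling is deterministic given the seed).
#' @return a list with `fixed` and `moving` landmark sets (see
#'   [landmark_set()]), in phase-i and phase-j frames respectively, plus the
#'   reference points as attribute `reference`.
#' @export
phantom_landmarks <- function(spec, breathing, n_points, phase_i, phase_j,
                              grid, seed = 1L) {
  if (n_points < 0) stop("n_points must be >= 0")
  lo <- pmax(grid$origin - grid$spacing / 2,
             spec$body_center - spec$body_semiaxes)
  hi <- pmin(grid$origin + (grid$dims - 0.5) * grid$spacing,
             spec$body_center + spec$body_semiaxes)
  if (any(lo >= hi)) stop("no lung region inside the grid")
  pts <- matrix(numeric(0), ncol = 3)
  if (n_points > 0) {
    set.seed(seed)
    got <- 0
    tries <- 0
    acc <- matrix(NA_real_, n_points, 3)
    while (got < n_points) {
      tries <- tries + 1
      if (tries > 200) stop("no lung voxels found inside the grid")
      m <- max(1000L, 4L * (n_points - got))
      cand <- cbind(stats::runif(m, lo[1], hi[1]),
                    stats::runif(m, lo[2], hi[2]),
                    stats::runif(m, lo[3], hi[3]))
      ok <- phantom_lung_membership(spec, cand)
      take <- min(sum(ok), n_points - got)
      if (take > 0) acc[got + seq_len(take), ] <- cand[which(ok)[seq_len(take)], ]
      got <- got + take
    }
    pts <- acc
  }
  fixed <- deform_points(breathing, pts, phase_i)
  moving <- deform_points(breathing, pts, phase_j)
  out <- list(fixed = landmark_set(fixed, grid$spacing, grid$origin),
              moving = landmark_set(moving, grid$spacing, grid$origin))
  attr(out, "reference") <- pts
  out
}

#' Simulated respiratory trace
#'
#' A surrogate amplitude signal emulating an external respiration monitor.
#' The amplitude is the (rescaled) superior diaphragm position
#' `1 - a(phi(t))`, maximal at the resting phase `phi = 0`, with optional
#' additive Gaussian noise. The ground-truth phase fraction
#' `phi(t) = (t / period) mod 1` is attached.
#'
#' @param duration_s trace length (s).
#' @param period_s breathing period (s).
#' @param sample_rate_hz sampling rate (Hz).
#' @param noise_sd additive amplitude noise standard deviation.
#' @param seed RNG seed.
#' @return an object of class `respiratory_signal` with fields `time`,
#'   `amplitude`, `phase` (ground-truth fraction) and `low_confidence`.
#' @export
breathing_trace <- function(duration_s = 60, period_s = 4,
                            sample_rate_hz = 10, noise_sd = 0, seed = 1L) {
  if (duration_s <= 0 || period_s <= 0 || sample_rate_hz <= 0)
    stop("duration, period and sample rate must be positive")
  t <- seq(0, duration_s, by = 1 / sample_rate_hz)
  phase <- (t / period_s) %% 1
  amp <- 1 - sin(pi * phase)^2
  if (noise_sd > 0) {
    set.seed(seed)
    amp <- amp + stats::rnorm(length(t), sd = noise_sd)
  }
  respiratory_signal(t, amp, phase = phase)
}

#' Respiratory signal container
#'
#' @param time strictly increasing sample times (s).
#' @param amplitude surrogate amplitude (arbitrary units).
#' @param phase optional ground-truth phase fraction per sample in `[0, 1)`.
#' @param low_confidence flag set by extraction when no moving edge is found.
#' @return an object of class `respiratory_signal`.
#' @export
respiratory_signal <- function(time, amplitude, phase = NULL,
                               low_confidence = FALSE) {
  if (any(diff(time) <= 0)) stop("sample times must be strictly increasing")
  if (!all(is.finite(amplitude))) stop("amplitude must be finite")
  structure(list(time = as.numeric(time), amplitude = as.numeric(amplitude),
                 phase = phase, low_confidence = low_confidence),
            class = "respiratory_signal")
}

#' Simulate a cone-beam scan of the breathing phantom
#'
#' Projection times are spread evenly over the trace; gantry angles are
#' spread evenly over 360 degrees. The continuous phase fraction at each
#' projection time is quantized to `n_motion_states` discrete motion states;
#' each state's phantom is rasterized once and ray-traced with exact Siddon
#' traversal. The noiseless line integrals l are converted to transmission
#' counts `I0 * exp(-l)`, Poisson noise applied (Gaussian approximation for
#' means above 1000 counts), and converted back to the line-integral domain.
#'
#' @inheritParams rasterize_phantom
#' @param trace a [breathing_trace()] (its ground-truth phase drives motion).
#' @param geometry a [cone_beam_geometry()].
#' @param n_projections number of projections over 360 degrees.
#' @param photons_I0 incident photon count per detector pixel; `Inf` for a
#'   noiseless scan.
#' @param seed RNG seed for the noise.
#' @param n_motion_states number of discrete motion states used to sample
#'   the breathing cycle.
#' @return a [projection_set()]; ground-truth per-projection phase fractions
#'   and the trace are attached as attribute `ground_truth`.
#' @export
simulate_scan <- function(spec, breathing, trace, geometry,
                          n_projections = 180, photons_I0 = Inf, seed = 1L,
                          grid = grid_spec(), n_motion_states = 20) {
  if (n_projections < 1) stop("need at least one projection")
  if (!is.infinite(photons_I0) && photons_I0 <= 0)
    stop("photons_I0 must be positive (or Inf for noiseless)")
  duration <- max(trace$time) - min(trace$time)
  times <- min(trace$time) + (seq_len(n_projections) - 1) / n_projections * duration
  angles <- (seq_len(n_projections) - 1) / n_projections * 2 * pi
  phase <- stats::approx(trace$time, trace$phase, xout = times,
                         rule = 2)$y %% 1
  state <- pmin(floor(phase * n_motion_states), n_motion_states - 1)
  data <- array(0, c(geometry$nu, geometry$nv, n_projections))
  for (s in sort(unique(state))) {
    frac <- (s + 0.5) / n_motion_states
    vol <- rasterize_phantom(spec, breathing, frac, grid)
    idx <- which(state == s)
    proj <- cpp_project(vol$data, grid$dims, grid$spacing, grid$origin,
                        angles[idx], geometry$sid, geometry$sdd,
                        geometry$nu, geometry$nv, geometry$du, geometry$dv)
    data[, , idx] <- proj
  }
  if (!is.infinite(photons_I0)) {
    set.seed(seed)
    mu <- photons_I0 * exp(-data)
    counts <- mu
    big <- mu > 1000
    counts[big] <- stats::rnorm(sum(big), mean = mu[big], sd = sqrt(mu[big]))
    counts[!big] <- stats::rpois(sum(!big), lambda = mu[!big])
    counts <- pmax(counts, 0.5)
    data <- array(-log(counts / photons_I0), dim(data))
  }
  out <- projection_set(data, angles, times, geometry)
  attr(out, "ground_truth") <- list(phase_fraction = phase, trace = trace,
                                    motion_state = state)
  out
}

#' Lung mask on a grid at a given phase
#'
#' @inheritParams rasterize_phantom
#' @return a logical array over the grid (TRUE inside lung tissue).
#' @export
lung_mask <- function(spec, breathing, grid, phase_fraction = 0) {
  co <- list(x = grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$spacing[1],
             y = grid$origin[2] + (seq_len(grid$dims[2]) - 1) * grid$spacing[2],
             z = grid$origin[3] + (seq_len(grid$dims[3]) - 1) * grid$spacing[3])
  pts <- as.matrix(expand.grid(x = co$x, y = co$y, z = co$z))
  ref <- pullback_points(breathing, pts, phase_fraction)
  array(phantom_lung_membership(spec, ref), grid$dims)
}
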