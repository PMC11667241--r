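# Shared fixtures, memoized so expensive simulations run once per session.

fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (!exists(key, envir = fx_cache)) assign(key, builder(), envir = fx_cache)
  get(key, envir = fx_cache)
}

# desk-scale breathing scan: 64x64x48 @ 4 mm, 180 projections, 10 phases,
# A = 10 mm, 4 s period, 60 s noiseless acquisition
fx_desk <- function() fx_memo("desk", function() {
  spec <- phantom_spec()
  br <- breathing_model(spec, amplitude = 10, period = 4)
  trace <- breathing_trace(60, 4, 10, 0, 1)
  grid <- grid_spec()
  projections <- simulate_scan(spec, br, trace, cone_beam_geometry(), 180,
                               Inf, 1, grid)
  signal <- extract_respiratory_signal(projections)
  binning <- phase_bin(signal, 10)
  list(spec = spec, br = br, trace = trace, grid = grid,
       projections = projections, signal = signal, binning = binning,
       gt = attr(projections, "ground_truth"))
})

# phase-correlated FDK, ground-truth phase volumes and ROI masks on the
# desk-scale scan
fx_desk_recon <- function() fx_memo("desk_recon", function() {
  d <- fx_desk()
  fdk4d <- reconstruct_phase_images(d$projections, d$binning, d$grid)
  gt4d <- phase_image_set(lapply((0:9) / 10, function(f)
    rasterize_phantom(d$spec, d$br, f, d$grid)))
  co <- voxel_coordinates(gt4d$volumes[[1]])
  pts <- as.matrix(expand.grid(x = co$x, y = co$y, z = co$z))
  body <- array(evaluate_phantom(d$spec, pts) > 0, d$grid$dims)
  lungs <- lapply(0:9, function(b) lung_mask(d$spec, d$br, d$grid, b / 10))
  list(fdk4d = fdk4d, gt4d = gt4d, body = body, lungs = lungs)
})

# self-supervised artifact reduction trained on the desk-scale scan
fx_desk_denoise <- function() fx_memo("desk_denoise", function() {
  d <- fx_desk()
  r <- fx_desk_recon()
  pairs <- make_training_pairs(d$projections, d$binning, d$grid)
  model <- train_artifact_reduction(pairs, epochs = 8, seed = 1)
  reduced <- apply_artifact_reduction(model, r$fdk4d)
  list(pairs = pairs, model = model, reduced = reduced,
       affine = attr(pairs, "affine"))
})

# one-shot motion model recovered from the artifact-reduced desk images
fx_desk_motion <- function() fx_memo("desk_motion", function() {
  dn <- fx_desk_denoise()
  res <- suppressWarnings(one_shot_register(
    dn$reduced, registration_config(seed = 1, max_iter = 120)))
  list(res = res, model = build_motion_model(res$dvfs))
})

# 4-phase parameter-recovery setup: A = 8 mm on the desk grid
fx_phase4 <- function() fx_memo("phase4", function() {
  spec <- phantom_spec()
  br <- breathing_model(spec, amplitude = 8, period = 4)
  grid <- grid_spec()
  fractions <- c(0, 0.25, 0.5, 0.75)
  vols <- lapply(fractions, function(f) rasterize_phantom(spec, br, f, grid))
  list(spec = spec, br = br, grid = grid, fractions = fractions,
       images = normalize_phase_images(phase_image_set(vols)))
})

fx_phase4_oneshot <- function() fx_memo("phase4_oneshot", function() {
  p4 <- fx_phase4()
  res <- one_shot_register(p4$images, registration_config(seed = 1))
  list(res = res, model = build_motion_model(res$dvfs))
})

# static uniform cylinder and its noiseless projections (FDK oracle)
fx_cylinder <- function() fx_memo("cylinder", function() {
  grid <- grid_spec()
  g <- cone_beam_geometry()
  mu <- 0.02
  radius <- 60
  vol <- array(0, grid$dims)
  co <- list(x = grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$spacing[1],
             y = grid$origin[2] + (seq_len(grid$dims[2]) - 1) * grid$spacing[2])
  rr <- outer(co$x^2, co$y^2, `+`)
  for (z in seq_len(grid$dims[3])) vol[, , z] <- ifelse(rr <= radius^2, mu, 0)
  angles <- (0:179) / 180 * 2 * pi
  proj <- moco4d:::cpp_project(vol, grid$dims, grid$spacing, grid$origin,
                               angles, g$sid, g$sdd, g$nu, g$nv, g$du, g$dv)
  roi <- array(FALSE, grid$dims)
  for (z in 16:32) roi[, , z] <- rr <= (radius * 0.6)^2
  list(grid = grid, geometry = g, mu = mu, radius = radius, vol = vol,
       projections = projection_set(proj, angles, seq_along(angles) / 3, g),
       roi = roi, rr = rr)
})

# smooth synthetic displacement field (half-period sinusoids, C1, gentle
# gradients) used by the transform-algebra oracles
smooth_field <- function(dims, amplitude) {
  co <- lapply(seq_along(dims), function(a) (seq_len(dims[a]) - 1) / (dims[a] - 1))
  g <- expand.grid(x = co[[1]], y = co[[2]], z = co[[3]])
  D <- array(0, c(dims, 3))
  D[, , , 1] <- amplitude * sin(pi * g$x) * sin(pi * g$y)
  D[, , , 2] <- amplitude * 0.6 * sin(pi * g$y) * sin(pi * g$z)
  D[, , , 3] <- amplitude * 0.8 * sin(pi * g$z) * sin(pi * g$x)
  D
}

# maximum displacement magnitude of a (nx,ny,nz,3) field
max_disp <- function(D) max(sqrt(apply(D^2, 1:3, sum)))

mean_disp_masked <- function(D, mask) mean(sqrt(apply(D^2, 1:3, sum))[mask])

# a smooth random test volume with non-constant windows everywhere
random_volume <- function(dims, seed = 1) {
  set.seed(seed)
  array(stats::runif(prod(dims)), dims)
}
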