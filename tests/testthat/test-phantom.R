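test_that("rasterization at phase 0 reproduces the static reference", {
  spec <- phantom_spec()
  br <- breathing_model(spec)
  grid <- grid_spec(c(24, 24, 18), c(12, 12, 12))
  v0 <- rasterize_phantom(spec, br, 0, grid)
  co <- voxel_coordinates(v0)
  pts <- as.matrix(expand.grid(x = co$x, y = co$y, z = co$z))
  expect_identical(v0$data, array(evaluate_phantom(spec, pts), grid$dims))
})

test_that("an all-air phantom rasterizes to zero and negative mu is rejected", {
  spec <- phantom_spec(mu_body = 0, mu_lung = 0, mu_tumor = 0, mu_bone = 0,
                       mu_vessel = 0)
  expect_error(phantom_spec(mu_body = 0.004), "mu_lung <= mu_body")
  expect_error(phantom_spec(mu_lung = -0.001), "non-negative")
  br <- breathing_model(spec)
  grid <- grid_spec(c(16, 16, 12), c(18, 18, 18))
  expect_true(all(rasterize_phantom(spec, br, 0.3, grid)$data == 0))
})

test_that("zero-attenuation check requires consistent ordering", {
  # mu_lung < mu_body < mu_bone must hold for the default tissue values
  spec <- phantom_spec()
  expect_lt(spec$mu_lung, spec$mu_body)
  expect_lt(spec$mu_body, spec$mu_bone)
})

test_that("the tumor centroid moves by the analytic Lagrangian displacement", {
  d <- fx_desk()
  v0 <- rasterize_phantom(d$spec, d$br, 0, d$grid)
  v5 <- rasterize_phantom(d$spec, d$br, 0.5, d$grid)
  co <- voxel_coordinates(v0)
  centroid <- function(v) {
    idx <- which(abs(v$data - d$spec$mu_tumor) < 1e-12, arr.ind = TRUE)
    c(mean(co$x[idx[, 1]]), mean(co$y[idx[, 2]]), mean(co$z[idx[, 3]]))
  }
  analytic <- d$br$amplitude *
    as.numeric(motion_weight(d$br, matrix(d$spec$tumor_center, 1)))
  shift <- centroid(v5) - centroid(v0)
  # within half a voxel (2 mm) per component
  expect_lt(max(abs(shift - analytic)), 2)
})

test_that("ground-truth displacement fields are identity at equal phases and
           inverse-consistent below 0.1 voxel up to 15 mm amplitude", {
  spec <- phantom_spec()
  grid <- grid_spec()
  br <- breathing_model(spec, amplitude = 15)
  expect_equal(max(abs(ground_truth_dvf(spec, br, 0.3, 0.3, grid))), 0)
  dab <- dvf_mm_to_voxel(ground_truth_dvf(spec, br, 0, 0.5, grid), grid$spacing)
  dba <- dvf_mm_to_voxel(ground_truth_dvf(spec, br, 0.5, 0, grid), grid$spacing)
  expect_lt(max_disp(compose_transforms(dba, dab)), 0.1)
})

test_that("displacement magnitude at the diaphragm apex is a(phi) * A", {
  spec <- phantom_spec()
  br <- breathing_model(spec, amplitude = 10)
  apex <- c(55, 0, spec$diaphragm_apex_z)
  grid <- grid_spec(c(2, 2, 2), c(2, 2, 2), origin = apex)
  d <- ground_truth_dvf(spec, br, 0, 0.5, grid)
  expect_equal(sqrt(sum(d[1, 1, 1, ]^2)), 10, tolerance = 1e-3)
})

test_that("rasterized phases equal the reference warped by the ground-truth
           field within 2% of the attenuation range", {
  d <- fx_desk()
  v0 <- rasterize_phantom(d$spec, d$br, 0, d$grid)
  v5 <- rasterize_phantom(d$spec, d$br, 0.5, d$grid)
  pull <- dvf_mm_to_voxel(ground_truth_dvf(d$spec, d$br, 0.5, 0, d$grid),
                          d$grid$spacing)
  w <- warp_image(v0, pull)
  expect_lt(mean(abs(w$data - v5$data)) / diff(range(v5$data)), 0.02)
})

test_that("phantom landmarks pair by the analytic motion and are seeded", {
  spec <- phantom_spec()
  br <- breathing_model(spec, amplitude = 10)
  grid <- grid_spec()
  empty <- phantom_landmarks(spec, br, 0, 0, 0.5, grid)
  expect_equal(length(empty$fixed), 0)
  lm <- phantom_landmarks(spec, br, 40, 0.1, 0.6, grid, seed = 3)
  ref <- attr(lm, "reference")
  dists <- sqrt(rowSums((lm$moving$points - lm$fixed$points)^2))
  a <- abs(phase_amplitude(br, 0.6) - phase_amplitude(br, 0.1))
  pred <- a * 10 * sqrt(rowSums(motion_weight(br, ref)^2))
  expect_equal(dists, pred, tolerance = 1e-10)
  lm2 <- phantom_landmarks(spec, br, 40, 0.1, 0.6, grid, seed = 3)
  expect_identical(lm$fixed$points, lm2$fixed$points)
  expect_identical(lm$moving$points, lm2$moving$points)
})

test_that("breathing traces have the requested cycle count and periodicity", {
  tr <- breathing_trace(60, 4, 10, 0)
  expect_equal(sum(diff(tr$phase) < -0.5), 15)
  tr17 <- breathing_trace(60, 60 / 17, 10, 0)
  expect_equal(sum(diff(tr17$phase) < -0.5), 17)
  # noiseless trace is exactly periodic
  per <- 4 * 10
  expect_equal(max(abs(tr$amplitude[1:(601 - per)] -
                         tr$amplitude[(per + 1):601])), 0)
  expect_error(breathing_trace(0, 4, 10), "positive")
})

test_that("central-ray line integrals match the analytic chord length", {
  cy <- fx_cylinder()
  g <- cy$geometry
  # the two rays closest to the detector center pass within du/2 of the axis
  cu <- (g$nu + 1) / 2
  cv <- (g$nv + 1) / 2
  vals <- cy$projections$data[c(floor(cu), ceiling(cu)),
                              c(floor(cv), ceiling(cv)), 1]
  expect_equal(mean(vals), 2 * cy$radius * cy$mu, tolerance = 0.01)
})

test_that("simulated projections of an empty phantom are exactly zero", {
  spec <- phantom_spec(mu_body = 0, mu_lung = 0, mu_tumor = 0, mu_bone = 0,
                       mu_vessel = 0)
  br <- breathing_model(spec)
  tr <- breathing_trace(8, 4, 5, 0)
  ps <- simulate_scan(spec, br, tr, cone_beam_geometry(nu = 32, nv = 24,
                                                       du = 14, dv = 14),
                      8, Inf, 1, grid_spec(c(16, 16, 12), c(16, 16, 16)))
  expect_true(all(ps$data == 0))
})

test_that("Poisson noise is unbiased and its variance halves at double flux", {
  cy <- fx_cylinder()
  spec <- phantom_spec()
  br <- breathing_model(spec, amplitude = 0)
  tr <- breathing_trace(8, 4, 5, 0)
  g <- cone_beam_geometry(nu = 32, nv = 24, du = 14, dv = 14)
  grid <- grid_spec(c(16, 16, 12), c(16, 16, 16))
  clean <- simulate_scan(spec, br, tr, g, 4, Inf, 1, grid)
  v1 <- v2 <- bias <- numeric(0)
  for (s in 1:25) {
    n1 <- simulate_scan(spec, br, tr, g, 4, 1e5, s, grid)
    n2 <- simulate_scan(spec, br, tr, g, 4, 2e5, s + 1000, grid)
    r1 <- n1$data - clean$data
    r2 <- n2$data - clean$data
    bias <- c(bias, mean(r1))
    v1 <- c(v1, stats::var(as.numeric(r1)))
    v2 <- c(v2, stats::var(as.numeric(r2)))
  }
  expect_lt(abs(mean(bias)), 3 * sqrt(mean(v1) / (25 * length(clean$data))))
  expect_equal(mean(v2) / mean(v1), 0.5, tolerance = 0.2)
})

test_that("the same seed reproduces a projection set bit for bit", {
  spec <- phantom_spec()
  br <- breathing_model(spec)
  tr <- breathing_trace(8, 4, 5, 0)
  g <- cone_beam_geometry(nu = 32, nv = 24, du = 14, dv = 14)
  grid <- grid_spec(c(16, 16, 12), c(16, 16, 16))
  a <- simulate_scan(spec, br, tr, g, 6, 5e4, 42, grid)
  b <- simulate_scan(spec, br, tr, g, 6, 5e4, 42, grid)
  expect_identical(a$data, b$data)
  expect_error(simulate_scan(spec, br, tr, g, 6, -1, 1, grid), "positive")
})
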