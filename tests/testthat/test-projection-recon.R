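test_that("the shroud surrogate is flat without motion and tracks breathing", {
  d <- fx_desk()
  gt_amp <- 1 - sin(pi * d$gt$phase_fraction)^2
  expect_gt(stats::cor(d$signal$amplitude, gt_amp), 0.9)
  expect_false(d$signal$low_confidence)
  # no-motion control on a finer rasterization (the 4 mm voxelization adds
  # broadband moire jitter unrelated to the extractor)
  static_br <- breathing_model(d$spec, amplitude = 0, period = 4)
  fine <- grid_spec(c(128, 128, 96), c(2, 2, 2))
  ps0 <- simulate_scan(d$spec, static_br, d$trace, cone_beam_geometry(), 90,
                       Inf, 1, fine)
  sig0 <- extract_respiratory_signal(ps0)
  expect_lt(stats::sd(sig0$amplitude), 0.01 * diff(range(d$signal$amplitude)))
})

test_that("the extracted signal's dominant frequency is the breathing rate", {
  d <- fx_desk()
  n <- length(d$signal$amplitude)
  sp <- Mod(stats::fft(d$signal$amplitude - mean(d$signal$amplitude)))
  k <- which.max(sp[2:floor(n / 2)])          # cycles over the record
  f <- k / diff(range(d$signal$time))
  expect_equal(f, 0.25, tolerance = 0.02)
})

test_that("phase binning maps peaks to fraction zero and partitions evenly", {
  # single bin takes everything
  sig <- respiratory_signal(seq(0, 30, 0.25), cos(2 * pi * seq(0, 30, 0.25) / 4))
  b1 <- phase_bin(sig, 1)
  expect_true(all(b1$bin == 0))
  # 15 cycles sampled 10x per cycle: occupancies equal within 1
  t <- seq(0, 60, length.out = 151)[-151]
  b <- phase_bin(respiratory_signal(t, cos(2 * pi * t / 4)), 10)
  occ <- tabulate(b$bin + 1L, 10)
  expect_lte(diff(range(occ)), 1)
  expect_equal(sum(occ), length(t))
  # peaks map to fraction ~0
  peaks_idx <- vapply(b$peak_times, function(pt) which.min(abs(t - pt)), 1L)
  expect_lt(max(moco4d:::circular_diff(b$fraction[peaks_idx], 0)), 0.02)
  expect_error(phase_bin(respiratory_signal(1:5, rep(0, 5)), 10),
               "cannot establish cycles")
})

test_that("assigned fractions agree with the simulator's ground truth", {
  d <- fx_desk()
  mae <- mean(moco4d:::circular_diff(d$binning$fraction, d$gt$phase_fraction))
  expect_lt(mae, 0.05)
  gtb <- phase_binning_from_fractions(d$gt$phase_fraction, 10)
  expect_gt(mean(d$binning$bin == gtb$bin), 0.9)
  # binning is a partition for every configuration
  for (nb in c(1, 3, 10))
    expect_equal(sum(tabulate(phase_bin(d$signal, nb)$bin + 1L, nb)),
                 n_projections(d$projections))
})

test_that("ramp filtering is zero on zero and constant rows and matches the
           DC-free closed-form kernel on an impulse", {
  g <- cone_beam_geometry()
  z <- projection_set(array(0, c(g$nu, g$nv, 2)), c(0, 1), c(0, 1), g)
  expect_equal(max(abs(ramp_filter(z)$data)), 0)
  const <- projection_set(array(5, c(g$nu, g$nv, 2)), c(0, 1), c(0, 1), g)
  expect_lt(max(abs(ramp_filter(const)$data)), 1e-6 * 5)
  imp <- array(0, c(g$nu, g$nv, 1)); imp[20, 1, 1] <- 1
  out <- ramp_filter(projection_set(imp, 0, 0, g))$data[, 1, 1]
  du <- g$du * g$sid / g$sdd
  L <- 2^ceiling(log2(2 * g$nu))
  h <- numeric(L)
  h[1] <- 1 / (4 * du^2)
  odd <- seq(1, L / 2, by = 2)
  h[1 + odd] <- -1 / (pi^2 * odd^2 * du^2)
  h[L + 1 - odd] <- -1 / (pi^2 * odd^2 * du^2)
  h <- h - mean(h)                      # DC-free variant of the closed form
  expected <- h[((seq_len(g$nu) - 20) %% L) + 1] * du
  expect_equal(out, expected, tolerance = 1e-6)
})

test_that("FDK reconstructs a uniform cylinder to within 5% attenuation", {
  cy <- fx_cylinder()
  rec <- fdk_reconstruct(cy$projections, cy$grid)
  expect_equal(mean(rec$data[cy$roi]), cy$mu, tolerance = 0.05)
})

test_that("FDK is linear and zero on zero projections", {
  cy <- fx_cylinder()
  sub <- projection_set(cy$projections$data[, , 1:12],
                        cy$projections$angles[1:12],
                        cy$projections$times[1:12], cy$geometry)
  grid <- grid_spec(c(24, 24, 16), c(8, 8, 8))
  r1 <- fdk_reconstruct(sub, grid)
  zero <- projection_set(sub$data * 0, sub$angles, sub$times, cy$geometry)
  expect_equal(max(abs(fdk_reconstruct(zero, grid)$data)), 0)
  combo <- projection_set(2 * sub$data, sub$angles, sub$times, cy$geometry)
  expect_equal(fdk_reconstruct(combo, grid)$data, 2 * r1$data,
               tolerance = 1e-10)
})

test_that("undersampled (phase-binned) FDK is strictly worse than the fully
           sampled reconstruction", {
  cy <- fx_cylinder()
  full <- fdk_reconstruct(cy$projections, cy$grid)
  idx <- seq(1, 180, by = 10)
  sub <- projection_set(cy$projections$data[, , idx],
                        cy$projections$angles[idx],
                        cy$projections$times[idx], cy$geometry)
  sparse <- fdk_reconstruct(sub, cy$grid)
  roi <- cy$roi
  expect_gt(sqrt(mean((sparse$data[roi] - cy$vol[roi])^2)),
            sqrt(mean((full$data[roi] - cy$vol[roi])^2)))
})

test_that("half-fan geometry and empty bins are rejected with clear errors", {
  expect_error(cone_beam_geometry(full_fan = FALSE), "half-fan")
  cy <- fx_cylinder()
  binning <- phase_binning_from_fractions(rep(0.01, 180), 10)
  expect_error(fdk_reconstruct(cy$projections, cy$grid, binning, 5L),
               "bin 5")
})

test_that("phase-correlated volumes use disjoint projection subsets covering
           the scan and track the tumor", {
  d <- fx_desk()
  r <- fx_desk_recon()
  expect_equal(r$fdk4d$n, 10)
  occ <- tabulate(d$binning$bin + 1L, 10)
  expect_equal(sum(occ), 180)
  expect_true(all(occ > 0))
  # tumor centroid oscillation across phases matches the analytic range
  co <- voxel_coordinates(r$fdk4d$volumes[[1]])
  zc <- vapply(r$fdk4d$volumes, function(v) {
    m <- v$data > 0.5 * d$spec$mu_tumor
    # restrict to the tumor neighborhood
    box <- abs(outer(co$x, rep(1, length(co$y))) - d$spec$tumor_center[1]) < 25
    idx <- which(m & array(box, dim(v$data)), arr.ind = TRUE)
    idx <- idx[abs(co$y[idx[, 2]] - d$spec$tumor_center[2]) < 25 &
                 abs(co$z[idx[, 3]] - d$spec$tumor_center[3]) < 30, ,
               drop = FALSE]
    mean(co$z[idx[, 3]])
  }, 0)
  u <- motion_weight(d$br, matrix(d$spec$tumor_center, 1))
  analytic_range <- abs(u[3]) * d$br$amplitude   # a(phi) spans [0, 1]
  expect_equal(diff(range(zc)), analytic_range,
               tolerance = 0.2 * analytic_range + 2)
})

test_that("one-bin phase reconstruction equals the all-projection FDK", {
  cy <- fx_cylinder()
  binning <- phase_binning_from_fractions(rep(0.001, 180), 1)
  grid <- grid_spec(c(24, 24, 16), c(8, 8, 8))
  one <- reconstruct_phase_images(cy$projections, binning, grid)
  all <- fdk_reconstruct(cy$projections, grid)
  expect_equal(one$volumes[[1]]$data, all$data, tolerance = 1e-12)
})
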