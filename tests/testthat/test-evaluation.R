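test_that("TRE is zero on identical sets and under exact compensation", {
  set.seed(1)
  pts <- matrix(runif(60, 10, 90), ncol = 3)
  fixed <- landmark_set(pts, c(1, 1, 1))
  expect_equal(compute_tre(fixed, fixed)$mean, 0)
  moving <- landmark_set(sweep(pts, 2, c(5, 0, 0), `+`), c(1, 1, 1))
  dvf <- array(0, c(100, 100, 100, 3))
  dvf[, , , 1] <- 5
  attr(dvf, "units") <- "mm"
  res <- compute_tre(fixed, moving, dvf, spacing = c(1, 1, 1),
                     origin = c(0, 0, 0))
  expect_equal(res$mean, 0, tolerance = 1e-9)
  expect_error(compute_tre(fixed, landmark_set(pts[1:10, ])), "length")
})

test_that("DIR-Lab landmark files parse, convert and round-trip losslessly", {
  path <- tempfile()
  writeLines(c("1 1 1", "11 1 1"), path)
  lm <- read_dirlab_landmarks(path, spacing = c(1, 1, 1))
  expect_equal(sqrt(sum((lm$points[1, ] - lm$points[2, ])^2)), 10)
  # empty file -> empty set
  writeLines(character(0), path)
  expect_equal(length(read_dirlab_landmarks(path, c(1, 1, 1))), 0)
  # malformed line reports its number
  writeLines(c("1 2 3", "4 five 6"), path)
  expect_error(read_dirlab_landmarks(path, c(1, 1, 1)), "line 2")
  # lossless round trip at DIR-Lab-like spacing
  set.seed(2)
  idx <- matrix(sample(1:256, 90, replace = TRUE), ncol = 3)
  sp <- c(0.97, 0.97, 2.5)
  lm0 <- landmark_set(sweep(idx - 1, 2, sp, `*`), sp)
  out <- tempfile()
  write_dirlab_landmarks(lm0, out)
  back <- read_dirlab_landmarks(out, sp)
  expect_equal(back$points, lm0$points, tolerance = 1e-9)
})

test_that("a 300-line landmark file yields 300 points", {
  path <- tempfile()
  set.seed(3)
  writeLines(apply(matrix(sample(1:200, 900, replace = TRUE), ncol = 3), 1,
                   paste, collapse = " "), path)
  expect_equal(length(read_dirlab_landmarks(path, c(1, 1, 2.5))), 300)
})

test_that("mean-aligned RMSE ignores offsets and recovers noise levels", {
  g <- random_volume(c(24, 24, 20), 4)
  mask <- array(TRUE, dim(g))
  expect_equal(rmse_mean_aligned(g + 0.37, g, mask), 0, tolerance = 1e-12)
  expect_equal(rmse_mean_aligned(g, g, mask), 0)
  set.seed(5)
  sigma <- 0.05
  noisy <- g + rnorm(length(g), sd = sigma)
  expect_equal(rmse_mean_aligned(noisy, g, mask), sigma, tolerance = 0.05)
  expect_error(rmse_mean_aligned(g, g, array(FALSE, dim(g))), "empty")
})

test_that("PSNR follows its closed-form relations", {
  g <- random_volume(c(16, 16, 12), 6)
  mask <- array(TRUE, dim(g))
  expect_equal(psnr(g, g, mask), Inf)
  peak <- max(g)
  set.seed(7)
  e1 <- rnorm(length(g)); e1 <- e1 - mean(e1)
  r1 <- g + array(0.02 * e1 / sqrt(mean(e1^2)), dim(g))
  r2 <- g + array(0.01 * e1 / sqrt(mean(e1^2)), dim(g))
  expect_equal(psnr(r2, g, mask) - psnr(r1, g, mask), 20 * log10(2),
               tolerance = 1e-6)
  # MSE = peak^2 gives 0 dB
  r0 <- g + array(peak * e1 / sqrt(mean(e1^2)), dim(g))
  expect_equal(psnr(r0, g, mask), 0, tolerance = 1e-6)
})

test_that("the SSIM scale search recovers inverse scalings and never does
           worse than scale 1", {
  g <- random_volume(c(20, 20, 16), 8)
  g <- moco4d:::cpp_gauss3(g, dim(g), 1.2)    # smooth, structured image
  mask <- array(TRUE, dim(g))
  res <- ssim_optimal_scale(g, g, mask)
  expect_equal(res$ssim, 1, tolerance = 1e-9)
  expect_equal(res$scale, 1, tolerance = 0.02)
  res2 <- ssim_optimal_scale(2 * g, g, mask)
  expect_equal(res2$scale, 0.5, tolerance = 0.02)
  expect_equal(res2$ssim, 1, tolerance = 1e-6)
  drange <- diff(range(g))
  set.seed(9)
  for (i in 1:25) {
    pert <- g * runif(1, 0.3, 3) + array(rnorm(length(g), sd = 0.05), dim(g))
    s_at_1 <- moco4d:::ssim_masked(
      pert + (mean(g) - mean(pert)), g, which(mask), drange)
    expect_gte(ssim_optimal_scale(pert, g, mask)$ssim, s_at_1 - 1e-9)
  }
  expect_error(ssim_optimal_scale(g, array(1, dim(g)), mask), "variance")
})

test_that("evaluation reports are complete and byte-deterministic", {
  set.seed(10)
  vols <- lapply(1:2, function(i)
    cbct_volume(random_volume(c(12, 12, 8), i)))
  gt <- phase_image_set(lapply(vols, function(v)
    cbct_volume(moco4d:::cpp_gauss3(v$data, dim(v$data), 1), v$spacing)))
  recs <- list(self = gt,
               noisy = phase_image_set(lapply(gt$volumes, function(v)
                 cbct_volume(v$data + 0.01, v$spacing))))
  masks <- list(all = array(TRUE, c(12, 12, 8)),
                half = array(rep(c(TRUE, FALSE), each = 576), c(12, 12, 8)))
  rep1 <- evaluate_pipeline(recs, gt, masks)
  expect_equal(nrow(rep1$table), 2 * 2 * 2)
  self_rows <- rep1$table[rep1$table$method == "self", ]
  expect_true(all(self_rows$rmse == 0))
  expect_true(all(abs(self_rows$ssim - 1) < 1e-12))
  noisy_rows <- rep1$table[rep1$table$method == "noisy", ]
  expect_true(all(noisy_rows$rmse < 1e-12))   # constant offset removed
  p1 <- tempfile(); p2 <- tempfile()
  write_report(rep1, p1)
  write_report(evaluate_pipeline(recs, gt, masks), p2)
  expect_identical(readBin(paste0(p1, ".json"), "raw", 1e6),
                   readBin(paste0(p2, ".json"), "raw", 1e6))
})

test_that("volumes survive a NIfTI round trip with spacing metadata", {
  v <- cbct_volume(random_volume(c(10, 9, 8), 11) * 0.02, c(4, 4, 4))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  back <- read_volume(path, origin = v$origin)
  expect_equal(back$data, v$data, tolerance = 1e-7)
  expect_equal(back$spacing, v$spacing)
})

test_that("projection sets round-trip through NIfTI plus JSON sidecar", {
  g <- cone_beam_geometry(nu = 16, nv = 12, du = 10, dv = 10)
  set.seed(12)
  ps <- projection_set(array(runif(16 * 12 * 5), c(16, 12, 5)),
                       seq(0, 2, length.out = 5), seq(0, 4, length.out = 5), g)
  path <- tempfile(fileext = ".nii.gz")
  write_projections(ps, path)
  back <- read_projections(path)
  expect_equal(back$data, ps$data, tolerance = 1e-6)
  expect_equal(back$angles, ps$angles, tolerance = 1e-12)
  expect_equal(back$geometry$sid, g$sid)
})
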