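test_that("percentile normalization clips, maps to [0,1] and inverts", {
  vol <- cbct_volume(array(5, c(6, 6, 4)))
  expect_warning(nz <- normalize_intensity(vol), "constant")
  expect_true(all(nz$data == 0))
  v <- cbct_volume(random_volume(c(12, 12, 8), 1) * 0.02)
  n <- normalize_intensity(v)
  expect_equal(range(n$data), c(0, 1), tolerance = 1e-12)
  back <- denormalize_intensity(n)
  q <- stats::quantile(v$data, c(0.005, 0.995), names = FALSE)
  clipped <- pmin(pmax(v$data, q[1]), q[2])
  expect_equal(back$data, clipped, tolerance = 1e-10)
})

test_that("pseudo-average bins partition projections and mix all phases", {
  d <- fx_desk()
  pseudo <- build_pseudo_average_bins(d$binning)
  occ <- tabulate(pseudo$bin + 1L, pseudo$n_bins)
  expect_equal(sum(occ), n_projections(d$projections))
  # every pseudo bin draws from many source phases across cycles
  prov <- pseudo$provenance
  phases_per_bin <- vapply(split(prov$source_phase, prov$pseudo_bin),
                           function(x) length(unique(x)), 1L)
  expect_true(all(phases_per_bin == 10))
  # the round-robin map averages per-cycle occupancy over all phases, so
  # pseudo bins are at least as balanced as the phase bins
  expect_lte(diff(range(occ)), diff(range(tabulate(d$binning$bin + 1L, 10))))
  single <- phase_binning_from_fractions(seq(0, 0.9, 0.1), 10,
                                         cycle = rep(0L, 10))
  expect_error(build_pseudo_average_bins(single), "one breathing cycle")
})

test_that("training pairs share the time-average target and undersampling
           makes inputs differ from it", {
  dn <- fx_desk_denoise()
  expect_length(dn$pairs, 10)
  for (pr in dn$pairs) {
    expect_identical(pr$target$data, dn$pairs[[1]]$target$data)
    expect_gt(sqrt(mean((pr$input$data - pr$target$data)^2)), 0)
  }
})

test_that("pseudo-average inputs carry time-averaged motion: their tumor
           centroid sits at the target's, unlike a real phase bin's", {
  d <- fx_desk()
  r <- fx_desk_recon()
  dn <- fx_desk_denoise()
  co <- voxel_coordinates(r$fdk4d$volumes[[1]])
  zc <- function(vol) {
    m <- vol$data > 0.5 * max(vol$data)
    idx <- which(m, arr.ind = TRUE)
    keep <- abs(co$x[idx[, 1]] - d$spec$tumor_center[1]) < 25 &
      abs(co$y[idx[, 2]] - d$spec$tumor_center[2]) < 25 &
      abs(co$z[idx[, 3]] - d$spec$tumor_center[3]) < 30
    mean(co$z[idx[keep, 3]])
  }
  z_target <- zc(dn$pairs[[1]]$target)
  z_pseudo <- vapply(dn$pairs, function(pr) zc(pr$input), 0)
  expect_lt(max(abs(z_pseudo - z_target)), d$grid$spacing[3])
  # the most displaced real phase bin (peak inhale) is farther away
  z_phase5 <- zc(r$fdk4d$volumes[[6]])
  expect_gt(abs(z_phase5 - z_target), max(abs(z_pseudo - z_target)))
})

test_that("training on identical input/target pairs learns the identity", {
  v <- cbct_volume(random_volume(c(16, 16, 12), 2), semantics = "normalized")
  pairs <- list(list(input = v, target = v))
  model <- train_artifact_reduction(pairs, epochs = 60, learning_rate = 5e-4,
                                    width = 4, seed = 1)
  expect_lt(utils::tail(model$loss_trace, 1), model$loss_trace[1])
  expect_lt(utils::tail(model$loss_trace, 1), 1e-3)
})

test_that("denoiser training is bit-reproducible under a fixed seed", {
  v <- cbct_volume(random_volume(c(12, 12, 8), 3), semantics = "normalized")
  t <- cbct_volume(random_volume(c(12, 12, 8), 4), semantics = "normalized")
  pairs <- list(list(input = v, target = t))
  a <- train_artifact_reduction(pairs, epochs = 3, width = 4, seed = 5)
  b <- train_artifact_reduction(pairs, epochs = 3, width = 4, seed = 5)
  expect_identical(a$params, b$params)
})

test_that("applying the model preserves geometry and handles flat input", {
  dn <- fx_desk_denoise()
  r <- fx_desk_recon()
  out <- dn$reduced
  for (i in seq_len(out$n)) {
    expect_equal(dim(out$volumes[[i]]$data), dim(r$fdk4d$volumes[[i]]$data))
    expect_equal(out$volumes[[i]]$spacing, r$fdk4d$volumes[[i]]$spacing)
    expect_true(all(is.finite(out$volumes[[i]]$data)))
  }
  flat <- phase_image_set(list(cbct_volume(array(0, c(64, 64, 48)),
                                           c(4, 4, 4),
                                           semantics = "normalized")))
  res <- apply_artifact_reduction(dn$model, flat)
  expect_true(all(is.finite(res$volumes[[1]]$data)))
})

test_that("artifact reduction lowers lung-ROI error against the ground truth
           for at least 8 of 10 phases and suppresses streak energy", {
  d <- fx_desk()
  r <- fx_desk_recon()
  dn <- fx_desk_denoise()
  gtn <- lapply(r$gt4d$volumes, function(v)
    moco4d:::apply_affine_norm(v, dn$affine))
  fdkn <- lapply(r$fdk4d$volumes, function(v)
    moco4d:::apply_affine_norm(v, dn$affine))
  wins <- 0
  for (i in 1:10) {
    mask <- r$lungs[[i]]
    if (rmse_mean_aligned(dn$reduced$volumes[[i]], gtn[[i]], mask) <
          rmse_mean_aligned(fdkn[[i]], gtn[[i]], mask))
      wins <- wins + 1
  }
  expect_gte(wins, 8)
  # residual high-frequency (streak) energy drops on axial slices
  hf_energy <- function(vol) {
    sl <- vol$data[, , 24]
    sp <- Mod(stats::fft(sl))^2
    n <- dim(sl)
    keep <- outer(pmin(0:(n[1] - 1), n[1] - 0:(n[1] - 1)) > n[1] / 4,
                  pmin(0:(n[2] - 1), n[2] - 0:(n[2] - 1)) > n[2] / 4)
    sum(sp[keep])
  }
  # compare against the model's own (per-phase normalized) input
  input1 <- normalize_intensity(r$fdk4d$volumes[[1]])
  expect_lt(hf_energy(dn$reduced$volumes[[1]]), hf_energy(input1))
})
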