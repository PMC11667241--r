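test_that("LNCC matches a brute-force windowed implementation", {
  f <- random_volume(c(9, 9, 9), 1)
  g <- random_volume(c(9, 9, 9), 2)
  r <- 2; eps <- 1e-5
  cl <- function(v) pmin(pmax(v, 1), 9)
  brute <- 0
  for (i in 1:9) for (j in 1:9) for (k in 1:9) {
    fw <- gw <- numeric(0)
    for (a in -r:r) for (b in -r:r) for (c in -r:r) {
      fw <- c(fw, f[cl(i + a), cl(j + b), cl(k + c)])
      gw <- c(gw, g[cl(i + a), cl(j + b), cl(k + c)])
    }
    A <- sum((fw - mean(fw)) * (gw - mean(gw)))
    brute <- brute + A^2 / (sum((fw - mean(fw))^2) * sum((gw - mean(gw))^2) + eps)
  }
  expect_equal(lncc(f, g, 5, eps), brute, tolerance = 1e-12)
})

test_that("LNCC is maximal and sign-blind on (anti-)identical images and
           near zero against a constant", {
  f <- random_volume(c(9, 9, 9), 3)
  expect_equal(lncc(f, f, 5, eps = 0), 9^3, tolerance = 1e-9)
  expect_equal(lncc(f, -f, 5, eps = 0), 9^3, tolerance = 1e-9)
  expect_equal(lncc(f, array(0.5, dim(f)), 5, eps = 1e-5), 0)
  expect_equal(lncc(f, f, 5, eps = 1e-5, normalize = TRUE), 1,
               tolerance = 1e-4)
})

test_that("similarity loss attains its lower bound on identical images at
           identity and exceeds it under perturbation", {
  dims <- c(10, 9, 8)
  N <- 3
  img <- random_volume(dims, 4)
  images <- phase_image_set(lapply(1:N, function(n)
    cbct_volume(img, semantics = "normalized")))
  z <- array(0, c(dims, 3, N))
  cfg0 <- registration_config(lncc_eps = 0, normalized_lncc = FALSE)
  expect_equal(similarity_loss(images, z, cfg0), -prod(dims),
               tolerance = 1e-9)
  # bound: never below -|Omega|
  set.seed(5)
  pert <- array(rnorm(length(z), sd = 0.4), dim(z))
  expect_gte(similarity_loss(images, pert, cfg0), -prod(dims))
  expect_gt(similarity_loss(images, pert, cfg0),
            similarity_loss(images, z, cfg0))
})

test_that("bending energy vanishes on affine fields, matches the stencil
           closed form, and is quadratic", {
  dims <- c(7, 7, 7)
  aff <- array(0, c(dims, 3, 1))
  co <- expand.grid(x = 1:7, y = 1:7, z = 1:7)
  aff[, , , 1, 1] <- array(0.5 * co$x - 0.2 * co$y + 3, dims)
  aff[, , , 2, 1] <- array(1.1 * co$z, dims)
  expect_equal(bending_energy(aff, 1), 0, tolerance = 1e-20)
  # D_x = x^2: interior second difference along x is exactly 2
  quad <- array(0, c(dims, 3, 1))
  quad[, , , 1, 1] <- array(co$x^2, dims)
  expected <- (2^2 * 5 * 49) / (3 * 1 * 343)   # 5 stencil rows per x-line
  expect_equal(bending_energy(quad, 1), expected, tolerance = 1e-12)
  expect_equal(bending_energy(2 * quad, 1), 4 * expected, tolerance = 1e-12)
})

test_that("temporal diffusion is zero for phase-constant fields, matches the
           two-phase closed form, and is order-sensitive", {
  dims <- c(6, 5, 4)
  cst <- array(1.7, c(dims, 3, 4))
  expect_equal(temporal_diffusion(cst, 1), 0)
  c0 <- c(0.3, -0.2, 0.5)
  D2 <- array(0, c(dims, 3, 2))
  for (cc in 1:3) D2[, , , cc, 2] <- c0[cc]
  expect_equal(temporal_diffusion(D2, 1), 2 * sum(c0^2) / (3 * 2),
               tolerance = 1e-12)
  # with a cyclic difference, N = 3 sums over all pairs regardless of order,
  # so order sensitivity needs N >= 4
  set.seed(6)
  D <- array(rnorm(prod(dims) * 12), c(dims, 3, 4))
  shuffled <- D[, , , , c(1, 3, 2, 4)]
  expect_false(isTRUE(all.equal(temporal_diffusion(D, 1),
                                temporal_diffusion(shuffled, 1))))
})

test_that("the zero-mean penalty vanishes on antisymmetric sets, matches the
           constant closed form, and ignores phase order", {
  dims <- c(6, 5, 4)
  set.seed(7)
  D1 <- array(rnorm(prod(dims) * 3), c(dims, 3, 1))
  anti <- array(0, c(dims, 3, 2))
  anti[, , , , 1] <- D1
  anti[, , , , 2] <- -D1
  expect_equal(zero_mean_penalty(anti, 0.05), 0)
  c0 <- c(0.3, -0.2, 0.5)
  N <- 4
  cst <- array(0, c(dims, 3, N))
  for (n in 1:N) for (cc in 1:3) cst[, , , cc, n] <- c0[cc]
  expect_equal(zero_mean_penalty(cst, 0.05),
               0.05 * N * sqrt(sum(c0^2)) / sqrt(3), tolerance = 1e-12)
  D <- array(rnorm(prod(dims) * 3 * N), c(dims, 3, N))
  expect_equal(zero_mean_penalty(D, 0.05),
               zero_mean_penalty(D[, , , , N:1], 0.05))
})

test_that("the total loss decomposes exactly into its four terms", {
  dims <- c(9, 8, 7)
  N <- 3
  images <- phase_image_set(lapply(1:N, function(n)
    cbct_volume(random_volume(dims, n), semantics = "normalized")))
  set.seed(8)
  dvfs <- array(rnorm(prod(dims) * 3 * N, sd = 0.4), c(dims, 3, N))
  cfg <- registration_config()
  tot <- total_loss(images, dvfs, cfg)
  terms <- attr(tot, "terms")
  expect_equal(as.numeric(tot), sum(unlist(terms)), tolerance = 1e-10)
  expect_equal(terms$similarity, similarity_loss(images, dvfs, cfg),
               tolerance = 1e-10)
  expect_equal(terms$bending, bending_energy(dvfs, cfg$lambda1),
               tolerance = 1e-10)
  expect_equal(terms$temporal,
               temporal_diffusion(dvfs, cfg$lambda2, cfg$cyclic_temporal),
               tolerance = 1e-10)
  expect_equal(terms$zero_mean, zero_mean_penalty(dvfs, cfg$lambda3),
               tolerance = 1e-10)
  # all-zero weights reduce to pure similarity
  cfg0 <- registration_config(lambda1 = 0, lambda2 = 0, lambda3 = 0)
  expect_equal(as.numeric(total_loss(images, dvfs, cfg0)),
               similarity_loss(images, dvfs, cfg0), tolerance = 1e-12)
  # each regularizer is non-negative
  expect_gte(terms$bending, 0)
  expect_gte(terms$temporal, 0)
  expect_gte(terms$zero_mean, 0)
})

test_that("the analytic loss gradient matches finite differences", {
  dims <- c(9, 8, 7)
  N <- 2
  images <- phase_image_set(lapply(1:N, function(n)
    cbct_volume(random_volume(dims, 10 + n), semantics = "normalized")))
  stack <- moco4d:::phase_stack(images)
  set.seed(9)
  dvfs <- array(rnorm(prod(dims) * 3 * N, sd = 0.4), c(dims, 3, N))
  cfg <- registration_config()
  lg <- moco4d:::total_loss_grad(stack, dvfs, cfg)
  eps <- 1e-6
  idx <- sample(length(dvfs), 6)
  for (i in idx) {
    dp <- dvfs; dp[i] <- dp[i] + eps
    dm <- dvfs; dm[i] <- dm[i] - eps
    fd <- (moco4d:::total_loss_grad(stack, dp, cfg)$loss -
             moco4d:::total_loss_grad(stack, dm, cfg)$loss) / (2 * eps)
    expect_equal(lg$grad[i], fd, tolerance = 1e-4)
  }
})

test_that("the implicit template is the mean of warped inputs and is
           permutation invariant", {
  dims <- c(8, 7, 6)
  a <- random_volume(dims, 11)
  b <- random_volume(dims, 12)
  images <- phase_image_set(list(cbct_volume(a, semantics = "normalized"),
                                 cbct_volume(b, semantics = "normalized")))
  z <- array(0, c(dims, 3, 2))
  tem <- implicit_template(images, z)
  expect_equal(tem$data, (a + b) / 2)
  swapped <- phase_image_set(list(cbct_volume(b, semantics = "normalized"),
                                  cbct_volume(a, semantics = "normalized")))
  expect_equal(implicit_template(swapped, z)$data, tem$data)
})
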