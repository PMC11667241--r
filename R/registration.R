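#' Phase image set
#'
#' The N phase-correlated volumes on one grid (initial, artifact-reduced or
#' motion-compensated).
#'
#' @param volumes list of [cbct_volume()] objects sharing one grid.
#' @return an object of class `phase_image_set`.
#' @export
phase_image_set <- function(volumes) {
  if (length(volumes) < 1) stop("need at least one volume")
  for (v in volumes[-1]) stopifnot_same_grid(volumes[[1]], v)
  structure(list(volumes = volumes, n = length(volumes),
                 spacing = volumes[[1]]$spacing,
                 origin = volumes[[1]]$origin),
            class = "phase_image_set")
}

#' @export
print.phase_image_set <- function(x, ...) {
  cat("<phase_image_set>", x$n, "phases,",
      paste(dim(x$volumes[[1]]$data), collapse = " x "), "voxels\n")
  invisible(x)
}

#' @export
length.phase_image_set <- function(x) x$n

# stack the phase images into an (nx,ny,nz,N) array
phase_stack <- function(images) {
  d <- dim(images$volumes[[1]]$data)
  arr <- array(0, c(d, images$n))
  for (n in seq_len(images$n)) arr[, , , n] <- images$volumes[[n]]$data
  arr
}

#' Normalize every phase image in a set
#'
#' Applies [normalize_intensity()] per phase.
#'
#' @param images a [phase_image_set()].
#' @return a normalized [phase_image_set()].
#' @export
normalize_phase_images <- function(images) {
  phase_image_set(lapply(images$volumes, normalize_intensity))
}

#' Registration configuration
#'
#' Hyperparameters of the groupwise registration. Defaults: spatial bending
#' energy weight `lambda1 = 1`, temporal diffusion weight
#' `lambda2 = 1e-5`, zero-mean deformation weight `lambda3 = 5e-2`, LNCC
#' window 5, Adam learning rate `1e-3`, convergence when the loss moves less
#' than `1e-5` from the moving average of the previous 20 iterations,
#' one-shot iteration cap 3000, and 200 epochs for population training.
#'
#' @param lambda1,lambda2,lambda3 non-negative regularization weights.
#' @param lncc_window odd LNCC window edge length (voxels).
#' @param lncc_eps stabilizer added to the LNCC denominator.
#' @param normalized_lncc divide the LNCC sum by the voxel count, making the
#'   similarity term the mean squared local correlation in `[-1, 0]` and
#'   grid-size independent (default). This puts the similarity on the same
#'   per-voxel scale as the regularizers, which is what makes the default
#'   weights meaningful; the raw sum-over-voxels variant is available by
#'   turning this off, but then the regularization weights must be rescaled
#'   by the voxel count to have any effect.
#' @param cyclic_temporal wrap the temporal forward difference from the last
#'   phase back to the first (respiratory phases are periodic).
#' @param learning_rate Adam step size.
#' @param converge_window,converge_tol convergence test parameters.
#' @param max_iter one-shot iteration cap.
#' @param population_epochs fixed epoch budget for population training.
#' @param batch_size training sets per update (population mode).
#' @param seed RNG seed for network initialization.
#' @param widths channel widths of the two internal network levels.
#' @param downsample internal grid reduction factor of the network.
#' @return a list of class `registration_config`.
#' @export
registration_config <- function(lambda1 = 1, lambda2 = 1e-5, lambda3 = 5e-2,
                                lncc_window = 5, lncc_eps = 1e-5,
                                normalized_lncc = TRUE,
                                cyclic_temporal = TRUE,
                                learning_rate = 1e-3,
                                converge_window = 20, converge_tol = 1e-5,
                                max_iter = 3000, population_epochs = 200,
                                batch_size = 1, seed = 1L,
                                widths = c(16, 32), downsample = 4) {
  if (any(c(lambda1, lambda2, lambda3) < 0)) stop("weights must be >= 0")
  if (lncc_window %% 2 != 1 || lncc_window < 3)
    stop("LNCC window must be odd and >= 3")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 lncc_window = as.integer(lncc_window), lncc_eps = lncc_eps,
                 normalized_lncc = normalized_lncc,
                 cyclic_temporal = cyclic_temporal,
                 learning_rate = learning_rate,
                 converge_window = as.integer(converge_window),
                 converge_tol = converge_tol, max_iter = as.integer(max_iter),
                 population_epochs = as.integer(population_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 widths = as.integer(widths), downsample = as.integer(downsample)),
            class = "registration_config")
}

as_array3 <- function(x) {
  if (is_cbct_volume(x)) x$data else x
}

#' Warp an image by a displacement field
#'
#' Pull convention: `out(p) = I(p + D(p))` with trilinear interpolation and
#' border-replicate sampling outside the grid. `D` is in voxel units on the
#' image's own grid, array `(nx, ny, nz, 3)` with components ordered
#' x (fastest grid axis), y, z.
#'
#' @param image a [cbct_volume()] or 3D array.
#' @param dvf displacement array `(nx, ny, nz, 3)` in voxels.
#' @return same type as `image`, warped.
#' @export
warp_image <- function(image, dvf) {
  arr <- as_array3(image)
  if (!identical(dim(arr), dim(dvf)[1:3]) || dim(dvf)[4] != 3L)
    stop("displacement field shape does not match the image grid")
  w <- cpp_warp(arr, dim(arr), dvf, FALSE)$value
  if (is_cbct_volume(image))
    cbct_volume(w, image$spacing, image$origin, image$semantics)
  else w
}

#' Implicit template of a groupwise registration
#'
#' The voxelwise mean of all warped phase images: the unbiased common
#' reference the groupwise registration aligns everything to.
#'
#' @param images a [phase_image_set()].
#' @param dvfs array `(nx, ny, nz, 3, N)` of voxel-unit displacements.
#' @return a [cbct_volume()].
#' @export
implicit_template <- function(images, dvfs) {
  stack <- phase_stack(images)
  d <- dim(stack)[1:3]
  acc <- array(0, d)
  for (n in seq_len(images$n))
    acc <- acc + cpp_warp(stack[, , , n], d, dvfs[, , , , n], FALSE)$value
  cbct_volume(acc / images$n, images$spacing, images$origin, "normalized")
}

# box-filter building blocks for the LNCC terms (replicate borders)
lncc_terms <- function(f, g, r, eps) {
  d <- dim(f)
  w <- (2 * r + 1)^3
  Bf <- cpp_boxsum3(f, d, r); Bg <- cpp_boxsum3(g, d, r)
  A <- cpp_boxsum3(f * g, d, r) - Bf * Bg / w
  Bv <- pmax(cpp_boxsum3(f * f, d, r) - Bf * Bf / w, 0)
  Cv <- pmax(cpp_boxsum3(g * g, d, r) - Bg * Bg / w, 0)
  list(A = A, Bv = Bv, Cv = Cv, Bf = Bf, Bg = Bg, den = Bv * Cv + eps, w = w)
}

#' Local normalized cross-correlation
#'
#' Sum over all voxels of the squared local correlation coefficient between
#' `f` and `g`, with local means over an `n^3` window centered at each voxel
#' (box filtering, replicate borders) and a small `eps` in the denominator.
#' The maximum is the voxel count, attained when every window is perfectly
#' (anti-)correlated.
#'
#' @param f,g volumes or 3D arrays on the same grid.
#' @param window odd window edge length (default 5).
#' @param eps denominator stabilizer (default 1e-5, normalized-intensity
#'   scale).
#' @param normalize divide by the voxel count.
#' @return a scalar.
#' @export
lncc <- function(f, g, window = 5, eps = 1e-5, normalize = FALSE) {
  f <- as_array3(f); g <- as_array3(g)
  if (!identical(dim(f), dim(g))) stop("f and g must share a grid")
  if (window %% 2 != 1) stop("window must be odd")
  tm <- lncc_terms(f, g, (window - 1) %/% 2, eps)
  val <- sum(tm$A^2 / tm$den)
  if (normalize) val / length(f) else val
}

# gradient of lncc wrt f and g
lncc_grad <- function(f, g, r, eps) {
  d <- dim(f)
  tm <- lncc_terms(f, g, r, eps)
  u1 <- 2 * tm$A / tm$den
  u2f <- tm$A^2 * tm$Cv / tm$den^2
  u2g <- tm$A^2 * tm$Bv / tm$den^2
  Bt <- function(x) cpp_boxsum3_adjoint(x, d, r)
  gf <- g * Bt(u1) - Bt(u1 * tm$Bg) / tm$w -
    2 * f * Bt(u2f) + 2 * Bt(u2f * tm$Bf) / tm$w
  gg <- f * Bt(u1) - Bt(u1 * tm$Bf) / tm$w -
    2 * g * Bt(u2g) + 2 * Bt(u2g * tm$Bg) / tm$w
  list(value = sum(tm$A^2 / tm$den), gf = gf, gg = gg)
}

#' Groupwise similarity loss
#'
#' Average negative LNCC between each warped phase image and the implicit
#' template: `-(1/N) * sum_n LNCC(I_n o T_n, I_tem)`. Lower is better; the
#' minimum is minus the voxel count.
#'
#' @inheritParams implicit_template
#' @param config a [registration_config()] (window, eps, normalization).
#' @return a scalar.
#' @export
similarity_loss <- function(images, dvfs, config = registration_config()) {
  stack <- phase_stack(images)
  d <- dim(stack)[1:3]
  N <- images$n
  warped <- array(0, c(d, N))
  for (n in seq_len(N))
    warped[, , , n] <- cpp_warp(stack[, , , n], d, dvfs[, , , , n], FALSE)$value
  tem <- apply(warped, 1:3, mean)
  tot <- 0
  for (n in seq_len(N))
    tot <- tot + lncc(warped[, , , n], tem, config$lncc_window,
                      config$lncc_eps, config$normalized_lncc)
  -tot / N
}

#' Spatial bending-energy regularizer
#'
#' `lambda1 / (3 N |Omega|) * sum` of squared second differences of each
#' displacement component along each spatial axis (forward differences
#' applied twice; the stencil is not evaluated where it would leave the
#' grid). Affine fields have zero energy.
#'
#' @inheritParams implicit_template
#' @param lambda1 weight.
#' @return a scalar (non-negative).
#' @export
bending_energy <- function(dvfs, lambda1 = 1) {
  d <- dim(dvfs)
  tot <- cpp_second_diff_energy(dvfs, d)$value
  lambda1 * tot / (3 * d[5] * prod(d[1:3]))
}

#' Temporal diffusion regularizer
#'
#' `lambda2 / (3 N |Omega|) * sum` of squared forward differences of the
#' displacement fields along the phase index, wrapping cyclically from the
#' last phase to the first (respiration is periodic); set
#' `cyclic = FALSE` for the open-ended variant.
#'
#' @inheritParams implicit_template
#' @param lambda2 weight.
#' @param cyclic wrap phase N back to phase 1.
#' @return a scalar (non-negative).
#' @export
temporal_diffusion <- function(dvfs, lambda2 = 1e-5, cyclic = TRUE) {
  d <- dim(dvfs)
  N <- d[5]
  if (N < 2) stop("need at least two phases")
  nxt <- if (cyclic) c(seq_len(N)[-1], 1L) else seq_len(N)[-1]
  cur <- if (cyclic) seq_len(N) else seq_len(N - 1)
  tot <- 0
  for (k in seq_along(cur))
    tot <- tot + sum((dvfs[, , , , nxt[k]] - dvfs[, , , , cur[k]])^2)
  lambda2 * tot / (3 * N * prod(d[1:3]))
}

#' Zero average deformation constraint
#'
#' `lambda3 * sqrt( (1 / (3 |Omega|)) * sum_p || sum_n D_n(p) ||^2 )`:
#' drives the sum of all phase-to-template displacements to zero so the
#' implicit template sits at the motion center.
#'
#' @inheritParams implicit_template
#' @param lambda3 weight.
#' @return a scalar (non-negative).
#' @export
zero_mean_penalty <- function(dvfs, lambda3 = 5e-2) {
  d <- dim(dvfs)
  S <- array(0, d[1:4])
  for (n in seq_len(d[5])) S <- S + dvfs[, , , , n]
  lambda3 * sqrt(sum(S^2) / (3 * prod(d[1:3])))
}

#' Total groupwise registration loss
#'
#' Similarity plus the three regularizers, each with its weight from the
#' configuration. Returns the total with the individual terms attached.
#'
#' @inheritParams similarity_loss
#' @return a scalar with attribute `terms` (named list of the four terms).
#' @export
total_loss <- function(images, dvfs, config = registration_config()) {
  terms <- list(
    similarity = similarity_loss(images, dvfs, config),
    bending = bending_energy(dvfs, config$lambda1),
    temporal = temporal_diffusion(dvfs, config$lambda2, config$cyclic_temporal),
    zero_mean = zero_mean_penalty(dvfs, config$lambda3))
  tot <- sum(unlist(terms))
  if (!is.finite(tot))
    stop("non-finite loss; terms: ",
         paste(names(terms), signif(unlist(terms), 6), sep = "=",
               collapse = ", "))
  attr(tot, "terms") <- terms
  tot
}

# loss and its gradient with respect to the full-resolution DVF array.
# Shares the warps between the similarity value and gradient.
total_loss_grad <- function(stack, dvfs, config) {
  d <- dim(stack)[1:3]
  N <- dim(stack)[4]
  nvox <- prod(d)
  r <- (config$lncc_window - 1) %/% 2
  warped <- vector("list", N)
  for (n in seq_len(N))
    warped[[n]] <- cpp_warp(stack[, , , n], d, dvfs[, , , , n], TRUE)
  tem <- array(0, d)
  for (n in seq_len(N)) tem <- tem + warped[[n]]$value
  tem <- tem / N
  scale <- if (config$normalized_lncc) 1 / nvox else 1
  sim <- 0
  gW <- vector("list", N)
  gT <- array(0, d)
  for (n in seq_len(N)) {
    lg <- lncc_grad(warped[[n]]$value, tem, r, config$lncc_eps)
    sim <- sim + lg$value
    gW[[n]] <- -scale / N * lg$gf
    gT <- gT - scale / N * lg$gg
  }
  sim <- -scale * sim / N
  grad <- array(0, dim(dvfs))
  for (n in seq_len(N)) {
    gWn <- gW[[n]] + gT / N      # template is the mean of the warps
    grad[, , , 1, n] <- gWn * warped[[n]]$gx
    grad[, , , 2, n] <- gWn * warped[[n]]$gy
    grad[, , , 3, n] <- gWn * warped[[n]]$gz
  }
  # bending energy
  d5 <- dim(dvfs)
  cb <- config$lambda1 / (3 * N * nvox)
  sd2 <- cpp_second_diff_energy(dvfs, d5)
  bend <- cb * sd2$value
  grad <- grad + cb * sd2$grad
  # temporal diffusion (cyclic or open)
  ct <- config$lambda2 / (3 * N * nvox)
  nxt <- if (config$cyclic_temporal) c(seq_len(N)[-1], 1L) else seq_len(N)[-1]
  cur <- if (config$cyclic_temporal) seq_len(N) else seq_len(N - 1)
  temp <- 0
  for (k in seq_along(cur)) {
    tk <- dvfs[, , , , nxt[k]] - dvfs[, , , , cur[k]]
    temp <- temp + sum(tk^2)
    grad[, , , , nxt[k]] <- grad[, , , , nxt[k]] + 2 * ct * tk
    grad[, , , , cur[k]] <- grad[, , , , cur[k]] - 2 * ct * tk
  }
  temp <- ct * temp
  # zero-mean constraint
  S <- array(0, d5[1:4])
  for (n in seq_len(N)) S <- S + dvfs[, , , , n]
  R <- sqrt(sum(S^2) / (3 * nvox))
  con <- config$lambda3 * R
  if (R > 1e-12) {
    gS <- config$lambda3 * S / (3 * nvox * R)
    for (n in seq_len(N)) grad[, , , , n] <- grad[, , , , n] + gS
  }
  list(loss = sim + bend + temp + con,
       terms = list(similarity = sim, bending = bend, temporal = temp,
                    zero_mean = con),
       grad = grad)
}
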