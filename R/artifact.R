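#' Pseudo-average projection binning
#'
#' Builds bins that mix respiratory phases across breathing cycles: pseudo
#' bin b receives, from cycle c, the projections whose phase label is
#' `(b + c) mod N` (cyclic round-robin). Each pseudo bin therefore has the
#' same undersampled angular distribution as a real phase bin but averages
#' over the whole breathing cycle, which makes FDK reconstructions of pseudo
#' bins blur motion exactly like the time-average image while keeping the
#' streak pattern of a phase bin - the property the self-supervised
#' artifact-reduction training exploits.
#'
#' @param binning a [phase_bin()] result (carries phase labels and cycle
#'   indices).
#' @param n_bins number of pseudo bins (defaults to the phase bin count).
#' @return an object of class `phase_binning` with `kind =
#'   "pseudo-average"` and a `provenance` data frame (projection, cycle,
#'   source phase, pseudo bin).
#' @export
build_pseudo_average_bins <- function(binning, n_bins = binning$n_bins) {
  if (length(unique(binning$cycle)) < 2)
    stop("cannot mix phases across cycles: only one breathing cycle")
  N <- binning$n_bins
  pseudo <- (binning$bin - binning$cycle) %% N
  if (n_bins != N) pseudo <- pseudo %% n_bins
  prov <- data.frame(projection = seq_along(pseudo),
                     cycle = binning$cycle,
                     source_phase = binning$bin,
                     pseudo_bin = pseudo)
  structure(list(n_bins = as.integer(n_bins), fraction = binning$fraction,
                 bin = as.integer(pseudo), cycle = binning$cycle,
                 peak_times = binning$peak_times, kind = "pseudo-average",
                 provenance = prov),
            class = "phase_binning")
}

# apply a stored normalization affine (clip to [0,1] afterwards)
apply_affine_norm <- function(vol, affine) {
  x <- (vol$data - affine$shift) * affine$scale
  cbct_volume(pmin(pmax(x, 0), 1), vol$spacing, vol$origin, "normalized")
}

#' Self-supervised training pairs for artifact reduction
#'
#' For each pseudo-average bin b: input = FDK reconstruction of pseudo bin
#' b, target = FDK reconstruction from all projections (the time-average
#' image). Both are normalized with the target's percentile-clip affine
#' parameters so input and target share one intensity scale.
#'
#' @param projections a [projection_set()].
#' @param binning a phase [phase_bin()] result.
#' @param grid a [grid_spec()].
#' @param window ramp apodization.
#' @return list of `list(input, target)` pairs of normalized
#'   [cbct_volume()]s, one per pseudo bin; the shared target and its affine
#'   are attached as attributes `target` and `affine`.
#' @export
make_training_pairs <- function(projections, binning, grid = grid_spec(),
                                window = "ram-lak") {
  pseudo <- build_pseudo_average_bins(binning)
  target_raw <- fdk_reconstruct(projections, grid, window = window)
  target <- normalize_intensity(target_raw)
  affine <- attr(target, "affine")
  pairs <- lapply(seq_len(pseudo$n_bins) - 1L, function(b) {
    inp <- fdk_reconstruct(projections, grid, pseudo, b, window)
    list(input = apply_affine_norm(inp, affine), target = target)
  })
  attr(pairs, "target") <- target
  attr(pairs, "affine") <- affine
  pairs
}

# ---- denoiser network ----------------------------------------------------

#' Streak-artifact-reduction model
#'
#' A small residual 3D encoder-decoder: a full-resolution stem convolution,
#' two residual blocks on a half-resolution grid, trilinear upsampling with
#' a skip connection, and a final convolution whose output is added to the
#' input (the network learns a correction). Instance normalization and
#' leaky ReLU (slope 0.2) throughout; trained with mean absolute error.
#'
#' @param width channel width.
#' @return an object of class `denoiser_spec`.
#' @export
denoiser_spec <- function(width = 8) {
  structure(list(width = as.integer(width)), class = "denoiser_spec")
}

#' @rdname denoiser_spec
#' @param spec a `denoiser_spec`.
#' @param seed RNG seed for initialization.
#' @return `build_denoiser`: an object of class `denoiser_model`.
#' @export
build_denoiser <- function(spec = denoiser_spec(), seed = 1L) {
  set.seed(seed)
  w <- spec$width
  params <- list(stem = conv_init(1L, w),
                 rb1 = resblock_init(w), rb2 = resblock_init(w),
                 fuse = conv_init(w, w),
                 out = conv_init(w, 1L))
  # keep the initial correction small so training starts near the identity
  params$out$w <- params$out$w * 0.01
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
            class = "denoiser_model")
}

denoiser_forward <- function(net, x3, want_cache = TRUE) {
  p <- net$params
  w <- net$spec$width
  padded <- pad_to_multiple(array(x3, c(dim(x3), 1L)), 2L)
  x <- padded$x
  dpad <- dim(x)[1:3]
  stem <- cnl_fwd(x, p$stem)
  pool <- cpp_avgpool(stem$y, dpad, w, 2L)
  dh <- dim(pool)[1:3]
  r1 <- resblock_fwd(pool, p$rb1)
  r2 <- resblock_fwd(r1$y, p$rb2)
  up <- cpp_resample(r2$y, dh, dpad, w)
  fuse <- cnl_fwd(up + stem$y, p$fuse)
  corr <- conv_fwd(fuse$y, p$out)
  ypad <- x + corr
  orig <- padded$orig
  y <- array(ypad[seq_len(orig[1]), seq_len(orig[2]), seq_len(orig[3]), 1],
             orig)
  cache <- if (want_cache)
    list(stem = stem, r1 = r1, r2 = r2, fuse = fuse, dpad = dpad, dh = dh,
         orig = orig)
  else NULL
  list(y = y, cache = cache)
}

denoiser_backward <- function(net, cache, grad_y) {
  p <- net$params
  w <- net$spec$width
  g <- array(0, c(cache$dpad, 1L))
  g[seq_len(cache$orig[1]), seq_len(cache$orig[2]),
    seq_len(cache$orig[3]), 1] <- grad_y
  bout <- conv_bwd(cache$fuse$y, p$out, g)
  bfuse <- cnl_bwd(cache$fuse, p$fuse, bout$gin)
  gup <- cpp_resample_adjoint(bfuse$gin, cache$dpad, cache$dh, w)
  b2 <- resblock_bwd(cache$r2, p$rb2, gup)
  b1 <- resblock_bwd(cache$r1, p$rb1, b2$gin)
  gpool <- cpp_avgpool_adjoint(b1$gin, cache$dh, w, 2L)
  bstem <- cnl_bwd(cache$stem, p$stem, gpool + bfuse$gin)
  list(stem = list(gw = bstem$gw, gb = bstem$gb),
       rb1 = b1$grads, rb2 = b2$grads,
       fuse = list(gw = bfuse$gw, gb = bfuse$gb),
       out = list(gw = bout$gw, gb = bout$gb))
}

#' Train the artifact-reduction network
#'
#' Minimizes the mean absolute error between the network output for each
#' pseudo-average input and the time-average target over a fixed number of
#' epochs with Adam. Training is per-scan (self-contained): the pairs come
#' from the scan being reconstructed, no external data.
#'
#' @param pairs training pairs from [make_training_pairs()].
#' @param epochs passes over the pairs.
#' @param learning_rate Adam step size.
#' @param width network channel width.
#' @param seed RNG seed (initialization; training itself is deterministic).
#' @param verbose print the loss each epoch.
#' @return a `denoiser_model` with the training `loss_trace` attached.
#' @export
train_artifact_reduction <- function(pairs, epochs = 20, learning_rate = 1e-3,
                                     width = 8, seed = 1L, verbose = FALSE) {
  if (length(pairs) < 1) stop("need at least one training pair")
  net <- build_denoiser(denoiser_spec(width), seed)
  state <- adam_init(net$params)
  trace <- numeric(0)
  for (ep in seq_len(epochs)) {
    for (pr in pairs) {
      x <- as_array3(pr$input)
      tgt <- as_array3(pr$target)
      fwd <- denoiser_forward(net, x)
      resid <- fwd$y - tgt
      loss <- mean(abs(resid))
      if (!is.finite(loss))
        stop("non-finite training loss; aborting (inputs out of range?)")
      trace <- c(trace, loss)
      gy <- sign(resid) / length(resid)
      grads <- denoiser_backward(net, fwd$cache, gy)
      st <- adam_step(net$params, grads, state, learning_rate)
      net$params <- st$params
      state <- st$state
    }
    if (verbose)
      message(sprintf("epoch %3d  MAE %.6f", ep,
                      mean(utils::tail(trace, length(pairs)))))
  }
  net$loss_trace <- trace
  net
}

#' Apply the artifact-reduction network to phase images
#'
#' Each phase volume is normalized (percentile clip to `[0, 1]`) if not
#' already, passed through the network, and returned on the same grid in
#' the normalized-intensity domain.
#'
#' @param model a trained `denoiser_model`.
#' @param images a [phase_image_set()].
#' @return a [phase_image_set()] of denoised, normalized volumes.
#' @export
apply_artifact_reduction <- function(model, images) {
  out <- lapply(images$volumes, function(v) {
    vn <- if (v$semantics == "normalized") v else normalize_intensity(v)
    y <- denoiser_forward(model, vn$data, want_cache = FALSE)$y
    if (!identical(dim(y), dim(vn$data)))
      stop("denoiser output shape mismatch")
    cbct_volume(y, v$spacing, v$origin, "normalized")
  })
  phase_image_set(out)
}
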