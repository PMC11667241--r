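# -------------------------------------------------------------------------
# Minimal 3D CNN machinery with hand-derived backpropagation.
#
# Layers: kernel-3 3D convolution (zero padding 1), instance normalization
# (no learnable affine), leaky ReLU, residual blocks, average pooling and
# trilinear up/down-sampling. Every forward pass records the caches needed
# for the exact backward pass; parameters are flat named lists of arrays so
# the Adam updater and serialization stay trivial.
# -------------------------------------------------------------------------

conv_init <- function(cin, cout, zero = FALSE) {
  if (zero) {
    w <- array(0, c(3, 3, 3, cin, cout))
  } else {
    sd <- sqrt(2 / (27 * cin))          # fan-in scaling
    w <- array(stats::rnorm(27 * cin * cout, sd = sd), c(3, 3, 3, cin, cout))
  }
  list(w = w, b = numeric(cout))
}

conv_fwd <- function(x, prm) {
  d <- dim(x)
  cpp_conv3(x, d[1:3], d[4], prm$w, prm$b, dim(prm$w)[5])
}

conv_bwd <- function(x, prm, gout) {
  d <- dim(x)
  gin <- cpp_conv3_bwd_input(gout, d[1:3], dim(prm$w)[5], prm$w, d[4])
  gwb <- cpp_conv3_bwd_weights(x, d[1:3], d[4], gout, dim(prm$w)[5])
  list(gin = gin, gw = gwb$gw, gb = gwb$gb)
}

IN_EPS <- 1e-5

instnorm_fwd <- function(x) {
  d <- dim(x)
  nv <- prod(d[1:3])
  y <- x
  istd <- numeric(d[4])
  for (c in seq_len(d[4])) {
    xc <- x[, , , c]
    mu <- mean(xc)
    v <- sum((xc - mu)^2) / nv
    istd[c] <- 1 / sqrt(v + IN_EPS)
    y[, , , c] <- (xc - mu) * istd[c]
  }
  list(y = y, istd = istd)
}

instnorm_bwd <- function(cache, gout) {
  d <- dim(gout)
  gx <- gout
  for (c in seq_len(d[4])) {
    gy <- gout[, , , c]
    y <- cache$y[, , , c]
    gx[, , , c] <- cache$istd[c] * (gy - mean(gy) - y * mean(gy * y))
  }
  gx
}

LRELU_SLOPE <- 0.2

lrelu_fwd <- function(x) ifelse(x > 0, x, LRELU_SLOPE * x)
lrelu_bwd <- function(x, gout) ifelse(x > 0, gout, LRELU_SLOPE * gout)

# conv -> instance norm -> leaky ReLU
cnl_fwd <- function(x, prm) {
  z <- conv_fwd(x, prm)
  ino <- instnorm_fwd(z)
  list(y = lrelu_fwd(ino$y), x = x, ino = ino)
}

cnl_bwd <- function(cache, prm, gout) {
  g <- lrelu_bwd(cache$ino$y, gout)
  g <- instnorm_bwd(cache$ino, g)
  conv_bwd(cache$x, prm, g)
}

# residual block: x + (conv-IN-lrelu-conv-IN), then leaky ReLU
resblock_fwd <- function(x, prm) {
  c1 <- cnl_fwd(x, prm$c1)
  z2 <- conv_fwd(c1$y, prm$c2)
  in2 <- instnorm_fwd(z2)
  s <- x + in2$y
  list(y = lrelu_fwd(s), x = x, c1 = c1, in2 = in2, s = s)
}

resblock_bwd <- function(cache, prm, gout) {
  gs <- lrelu_bwd(cache$s, gout)
  g2 <- instnorm_bwd(cache$in2, gs)
  b2 <- conv_bwd(cache$c1$y, prm$c2, g2)
  b1 <- cnl_bwd(cache$c1, prm$c1, b2$gin)
  list(gin = b1$gin + gs,
       grads = list(c1 = list(gw = b1$gw, gb = b1$gb),
                    c2 = list(gw = b2$gw, gb = b2$gb)))
}

resblock_init <- function(w) list(c1 = conv_init(w, w), c2 = conv_init(w, w))

#' Groupwise registration network specification
#'
#' A compact 3D U-Net/ResNet hybrid: the N-channel stack of phase images is
#' reduced to an internal grid (factor `downsample`), passed through an
#' encoder of four residual blocks on two resolution levels and a decoder of
#' three residual blocks with a skip connection, and mapped to `3 N`
#' displacement channels which are trilinearly upsampled back to the input
#' grid. Convolutions have kernel 3 with instance normalization and leaky
#' ReLU (slope 0.2); the final convolution is zero-initialized so the
#' untrained network predicts the identity transform.
#'
#' @param n_phases number of input phase images N.
#' @param widths channel widths of the two internal levels.
#' @param downsample integer reduction factor between the image grid and the
#'   network's first level.
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(n_phases, widths = c(16, 32), downsample = 4) {
  if (n_phases < 2) stop("need at least two phases")
  structure(list(n_phases = as.integer(n_phases),
                 widths = as.integer(widths),
                 downsample = as.integer(downsample),
                 out_channels = 3L * as.integer(n_phases)),
            class = "network_spec")
}

#' Build a registration network
#'
#' Initializes all parameters (He fan-in initialization under the given
#' seed; zero for the output layer, so the initial prediction is the
#' identity transform).
#'
#' @param spec a [network_spec()].
#' @param seed RNG seed for the initialization.
#' @return an object of class `registration_network`.
#' @export
build_network <- function(spec, seed = 1L) {
  set.seed(seed)
  w1 <- spec$widths[1]; w2 <- spec$widths[2]
  params <- list(
    stem = conv_init(spec$n_phases, w1),
    enc1 = resblock_init(w1), enc2 = resblock_init(w1),
    down = conv_init(w1, w2),
    enc3 = resblock_init(w2), enc4 = resblock_init(w2),
    up = conv_init(w2, w1),
    dec1 = resblock_init(w1), dec2 = resblock_init(w1),
    dec3 = resblock_init(w1),
    out = conv_init(w1, spec$out_channels, zero = TRUE))
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
            class = "registration_network")
}

#' @export
print.registration_network <- function(x, ...) {
  cat("<registration_network> N =", x$spec$n_phases, ", widths",
      paste(x$spec$widths, collapse = "/"), ", internal downsample",
      x$spec$downsample, ",", network_n_parameters(x), "parameters\n")
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param net a [build_network()] result.
#' @return integer parameter count.
#' @export
network_n_parameters <- function(net) {
  sum(vapply(rapply(net$params, length, how = "unlist"), identity, 0))
}

# pad spatial dims (replicating the last slice) up to a multiple of m
pad_to_multiple <- function(x, m) {
  d <- dim(x)
  tgt <- ceiling(d[1:3] / m) * m
  if (all(tgt == d[1:3])) return(list(x = x, orig = d[1:3]))
  idx <- lapply(1:3, function(a) pmin(seq_len(tgt[a]), d[a]))
  list(x = x[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE], orig = d[1:3])
}

# forward pass: input (nx,ny,nz,N) -> list(dvf (nx,ny,nz,3,N), cache)
network_forward <- function(net, input, want_cache = TRUE) {
  spec <- net$spec
  p <- net$params
  padded <- pad_to_multiple(input, spec$downsample * 2L)
  x <- padded$x
  dpad <- dim(x)[1:3]
  x0 <- cpp_avgpool(x, dpad, spec$n_phases, spec$downsample)
  d1 <- dim(x0)[1:3]
  stem <- cnl_fwd(x0, p$stem)
  e1 <- resblock_fwd(stem$y, p$enc1)
  e2 <- resblock_fwd(e1$y, p$enc2)
  pool <- cpp_avgpool(e2$y, d1, spec$widths[1], 2L)
  d2 <- dim(pool)[1:3]
  dn <- cnl_fwd(pool, p$down)
  e3 <- resblock_fwd(dn$y, p$enc3)
  e4 <- resblock_fwd(e3$y, p$enc4)
  upres <- cpp_resample(e4$y, d2, d1, spec$widths[2])
  up <- cnl_fwd(upres, p$up)
  skip <- up$y + e2$y
  dc1 <- resblock_fwd(skip, p$dec1)
  dc2 <- resblock_fwd(dc1$y, p$dec2)
  dc3 <- resblock_fwd(dc2$y, p$dec3)
  oc <- conv_fwd(dc3$y, p$out)
  full <- cpp_resample(oc, d1, dpad, spec$out_channels)
  orig <- padded$orig
  dvf <- array(full[seq_len(orig[1]), seq_len(orig[2]), seq_len(orig[3]), ],
               c(orig, 3L, spec$n_phases))
  cache <- if (want_cache)
    list(x0 = x0, stem = stem, e1 = e1, e2 = e2, pool_in_dims = d1,
         dn = dn, e3 = e3, e4 = e4, upres = upres, up = up, skip = skip,
         dc1 = dc1, dc2 = dc2, dc3 = dc3, d1 = d1, d2 = d2, dpad = dpad,
         orig = orig)
  else NULL
  list(dvf = dvf, cache = cache)
}

# backward pass: gradient wrt the full-resolution DVF -> parameter grads
network_backward <- function(net, cache, grad_dvf) {
  spec <- net$spec
  p <- net$params
  gfull <- array(0, c(cache$dpad, spec$out_channels))
  gfull[seq_len(cache$orig[1]), seq_len(cache$orig[2]),
        seq_len(cache$orig[3]), ] <-
    array(grad_dvf, c(cache$orig, spec$out_channels))
  goc <- cpp_resample_adjoint(gfull, cache$dpad, cache$d1, spec$out_channels)
  bout <- conv_bwd(cache$dc3$x, p$out, goc)
  b3 <- resblock_bwd(cache$dc3, p$dec3, bout$gin)
  b2 <- resblock_bwd(cache$dc2, p$dec2, b3$gin)
  b1 <- resblock_bwd(cache$dc1, p$dec1, b2$gin)
  gskip <- b1$gin
  bup <- cnl_bwd(cache$up, p$up, gskip)
  gup <- cpp_resample_adjoint(bup$gin, cache$d1, cache$d2, spec$widths[2])
  be4 <- resblock_bwd(cache$e4, p$enc4, gup)
  be3 <- resblock_bwd(cache$e3, p$enc3, be4$gin)
  bdn <- cnl_bwd(cache$dn, p$down, be3$gin)
  gpool <- cpp_avgpool_adjoint(bdn$gin, cache$d2, spec$widths[1], 2L)
  be2 <- resblock_bwd(cache$e2, p$enc2, gpool + gskip)
  be1 <- resblock_bwd(cache$e1, p$enc1, be2$gin)
  bstem <- cnl_bwd(cache$stem, p$stem, be1$gin)
  list(stem = list(gw = bstem$gw, gb = bstem$gb),
       enc1 = be1$grads, enc2 = be2$grads,
       down = list(gw = bdn$gw, gb = bdn$gb),
       enc3 = be3$grads, enc4 = be4$grads,
       up = list(gw = bup$gw, gb = bup$gb),
       dec1 = b1$grads, dec2 = b2$grads, dec3 = b3$grads,
       out = list(gw = bout$gw, gb = bout$gb))
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

# grads use gw/gb naming inside conv params; map onto w/b
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (!is.null(p$w)) {
      gl <- list(w = g$gw, b = g$gb)
      for (nm in c("w", "b")) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * gl[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * gl[[nm]]^2
        p[[nm]] <- p[[nm]] - lr * (m[[nm]] / bc1) / (sqrt(v[[nm]] / bc2) + eps)
      }
      return(list(p = p, m = m, v = v))
    }
    for (nm in names(p)) {
      r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# ---- serialization -------------------------------------------------------

#' Save / load a network to a JSON-headed text file
#'
#' Parameters are stored as flat numeric vectors in JSON together with the
#' architecture spec and seed, so models survive as plain text.
#'
#' @param net a network object (registration or denoiser).
#' @param path output path.
#' @return `path` invisibly; `load_network` returns the network.
#' @export
save_network <- function(net, path) {
  flat <- rapply(net$params, function(x) list(dim = dim(x) %||% length(x),
                                              data = as.numeric(x)),
                 how = "replace")
  obj <- list(class = class(net)[1], spec = unclass(net$spec),
              seed = net$seed, params = flat)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(x) {
    if (is.list(x) && !is.null(x$data)) {
      d <- unlist(x$dim)
      if (length(d) <= 1) return(as.numeric(x$data))
      return(array(as.numeric(x$data), dim = d))
    }
    lapply(x, rebuild)
  }
  spec <- obj$spec
  spec <- structure(lapply(spec, function(v) if (is.numeric(v)) as.integer(v) else v),
                    class = if (obj$class == "registration_network")
                      "network_spec" else "denoiser_spec")
  structure(list(spec = spec, params = rebuild(obj$params),
                 seed = as.integer(obj$seed)),
            class = obj$class)
}
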