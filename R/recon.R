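#' Extract a respiratory surrogate from projections (Amsterdam Shroud)
#'
#' Collapses each projection along the lateral detector axis into a 1D
#' column, stacks the columns over time into the shroud image, and enhances
#' edges with a vertical (axial) derivative. The detector row whose
#' derivative varies most over time locates the moving diaphragm edge; the
#' surrogate amplitude is the weighted centroid of the rectified derivative
#' within a window around that row (computed for both derivative polarities;
#' the candidate with the more concentrated spectrum, i.e. the periodic
#' breathing edge, is kept). The result is high-pass filtered and smoothed. The centroid
#' is in detector rows oriented along +z, so the surrogate is maximal when
#' the diaphragm sits superiorly (the resting end-exhale state).
#'
#' @param projections a [projection_set()] with at least 2 projections.
#' @return a [respiratory_signal()] at the projection timestamps. If no
#'   moving edge is detected (constant projections) the signal is flagged
#'   `low_confidence = TRUE` rather than raising an error.
#' @export
extract_respiratory_signal <- function(projections) {
  np <- n_projections(projections)
  if (np < 2) stop("need at least 2 projections")
  shroud <- apply(projections$data, c(2, 3), sum)      # (nv, nproj)
  grad <- shroud[-1, , drop = FALSE] - shroud[-nrow(shroud), , drop = FALSE]
  # row score: temporal variability after removing slow (gantry-rotation)
  # trends, so the breathing-frequency band dominates the row choice
  hp <- t(apply(grad, 1, function(r) r - running_mean(r, max(5L, round(np / 8)))))
  score <- apply(hp, 1, stats::sd)
  low_conf <- max(score) <= 1e-9 * max(1, max(abs(shroud)))
  r0 <- which.max(score)
  halfw <- max(4L, round(nrow(grad) * 0.1))
  sel <- max(1, r0 - halfw):min(nrow(grad), r0 + halfw)
  gs <- grad[sel, , drop = FALSE]
  # edge-position centroid for each derivative polarity; keep the candidate
  # whose spectrum is most concentrated (a periodic breathing edge), which
  # is robust to which side of the interface carries more energy
  centroid_hp <- function(w) {
    tot <- colSums(w)
    amp <- ifelse(tot > 0, colSums(w * sel) / pmax(tot, .Machine$double.xmin),
                  0)
    # high-pass against slow gantry-rotation drifts, then light smoothing
    # against detector/voxel discretization jitter
    amp <- amp - running_mean(amp, max(5L, round(np / 8)))
    running_mean(amp, 1L)
  }
  spectral_peak_fraction <- function(s) {
    p <- Mod(stats::fft(s - mean(s)))[2:max(2, floor(np / 2))]^2
    if (sum(p) <= 0) return(0)
    max(p) / sum(p)
  }
  amp_neg <- centroid_hp(pmax(-gs, 0))
  amp_pos <- centroid_hp(pmax(gs, 0))
  amp <- if (spectral_peak_fraction(amp_neg) >= spectral_peak_fraction(amp_pos))
    amp_neg else amp_pos
  tt <- projections$times
  fit <- stats::lm.fit(cbind(1, tt), amp)
  respiratory_signal(tt, fit$residuals, low_confidence = low_conf)
}

# centered running mean with edge-shrinking windows
running_mean <- function(x, halfw) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - halfw, 1)
  hi <- pmin(seq_len(n) + halfw, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# dominant period (in seconds) of a uniformly sampled signal via the
# discrete spectrum, ignoring the DC bin
dominant_period <- function(time, amplitude) {
  n <- length(amplitude)
  x <- amplitude - mean(amplitude)
  sp <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  sp[1] <- 0
  k <- which.max(sp) - 1            # cycles over the record
  if (k == 0) return(NA_real_)
  (max(time) - min(time)) * n / (n - 1) / k
}

#' Assign respiratory phase fractions and bins from a surrogate signal
#'
#' Detects peaks of the surrogate (local maxima with a minimum prominence
#' and a minimum separation of half the dominant period), assigns each
#' sample a phase fraction growing linearly in time between consecutive
#' peaks (peaks map to fraction 0), and labels bins so that bin 0 is
#' centered on the peaks: `bin = floor(((fraction + 1/(2 n_bins)) mod 1) *
#' n_bins)`. A cycle index (number of peaks passed) is attached for
#' pseudo-average binning.
#'
#' @param signal a [respiratory_signal()] sampled at the projection times.
#' @param n_bins number of respiratory phase bins (default 10).
#' @param min_prominence_frac minimum peak prominence as a fraction of the
#'   signal range.
#' @return an object of class `phase_binning` with fields `n_bins`,
#'   `fraction`, `bin` (0-based), `cycle`, `peak_times`, `kind = "phase"`.
#' @export
phase_bin <- function(signal, n_bins = 10, min_prominence_frac = 0.2) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  t <- signal$time
  z <- signal$amplitude
  n <- length(z)
  # light smoothing against pixel-level jitter
  if (n >= 5) z <- stats::filter(z, rep(1 / 3, 3), sides = 2) |>
      (\(v) { v[is.na(v)] <- z[is.na(v)]; as.numeric(v) })()
  period <- dominant_period(t, z)
  if (is.na(period)) stop("cannot establish cycles: no dominant frequency")
  dt <- stats::median(diff(t))
  min_sep <- period / 2
  rng <- diff(range(z))
  cand <- which(diff(sign(diff(z))) < 0) + 1L
  cand <- cand[order(z[cand], decreasing = TRUE)]
  peaks <- integer(0)
  for (i in cand) {
    if (all(abs(t[i] - t[peaks]) >= min_sep)) {
      # prominence: rise above the lowest point within half a period
      nb <- which(abs(t - t[i]) <= min_sep)
      if (z[i] - min(z[nb]) >= min_prominence_frac * rng)
        peaks <- c(peaks, i)
    }
  }
  peaks <- sort(peaks)
  if (length(peaks) < 2) stop("cannot establish cycles: fewer than 2 peaks")
  pt <- t[peaks]
  # linear phase between peaks; extrapolate the first/last partial cycle
  # with the neighboring cycle length
  frac <- numeric(n)
  cycle <- integer(n)
  first_len <- pt[2] - pt[1]
  last_len <- pt[length(pt)] - pt[length(pt) - 1]
  for (i in seq_len(n)) {
    k <- findInterval(t[i], pt)
    if (k == 0) {
      frac[i] <- ((t[i] - pt[1]) / first_len) %% 1
      cycle[i] <- -1L
    } else if (k == length(pt)) {
      frac[i] <- ((t[i] - pt[length(pt)]) / last_len) %% 1
      cycle[i] <- k - 1L
    } else {
      frac[i] <- (t[i] - pt[k]) / (pt[k + 1] - pt[k])
      cycle[i] <- k - 1L
    }
  }
  frac <- frac %% 1
  bin <- floor(((frac + 1 / (2 * n_bins)) %% 1) * n_bins)
  structure(list(n_bins = as.integer(n_bins), fraction = frac,
                 bin = as.integer(bin), cycle = cycle, peak_times = pt,
                 kind = "phase"),
            class = "phase_binning")
}

#' @rdname phase_bin
#' @param fraction per-projection phase fractions in `[0, 1)` (for example
#'   the simulator's ground truth).
#' @param cycle optional per-projection cycle indices.
#' @export
phase_binning_from_fractions <- function(fraction, n_bins = 10, cycle = NULL) {
  fraction <- fraction %% 1
  bin <- floor(((fraction + 1 / (2 * n_bins)) %% 1) * n_bins)
  if (is.null(cycle)) cycle <- cumsum(c(0, diff(fraction) < -0.5))
  structure(list(n_bins = as.integer(n_bins), fraction = fraction,
                 bin = as.integer(bin), cycle = as.integer(cycle),
                 peak_times = NULL, kind = "phase"),
            class = "phase_binning")
}

#' @export
print.phase_binning <- function(x, ...) {
  cat("<phase_binning>", length(x$fraction), "projections into", x$n_bins,
      paste0(x$kind, " bins; occupancy:"),
      paste(tabulate(x$bin + 1L, x$n_bins), collapse = " "), "\n")
  invisible(x)
}

# circular absolute difference between phase fractions
circular_diff <- function(a, b) {
  d <- abs((a - b) %% 1)
  pmin(d, 1 - d)
}

#' Ramp-filter projection rows
#'
#' Row-wise (along the lateral detector axis) convolution with the discrete
#' band-limited ramp kernel, computed in the frequency domain after padding
#' each row to at least twice its length (edge values are replicated into
#' the padding, which suppresses circular-convolution wrap-around and keeps
#' constant rows exactly constant). The kernel is constructed in the
#' spatial domain (the classical closed form: `1/(4 du^2)` at lag 0,
#' `-1/(pi^2 n^2 du^2)` at odd lags, 0 at even lags) with detector spacing
#' rescaled to the isocenter, and its DC component is removed so constant
#' rows map to zero. An optional Hann window apodizes the response.
#'
#' @param projections a [projection_set()].
#' @param window `"ram-lak"` (pure ramp) or `"hann"`.
#' @return a [projection_set()] with filtered rows.
#' @export
ramp_filter <- function(projections, window = c("ram-lak", "hann")) {
  window <- match.arg(window)
  g <- projections$geometry
  if (g$nu < 2) stop("row length must be >= 2")
  du_iso <- g$du * g$sid / g$sdd
  H <- ramp_response(g$nu, du_iso, window)
  L <- length(H)
  d <- dim(projections$data)
  rows <- matrix(0, L, d[2] * d[3])
  rows[seq_len(d[1]), ] <- matrix(projections$data, d[1])
  # replicate the row edges into the padding (split between both ends)
  nright <- (L - d[1]) %/% 2
  if (nright > 0)
    rows[d[1] + seq_len(nright), ] <-
      rows[rep(d[1], nright), , drop = FALSE]
  nleft <- L - d[1] - nright
  if (nleft > 0)
    rows[d[1] + nright + seq_len(nleft), ] <- rows[rep(1, nleft), , drop = FALSE]
  Q <- Re(stats::mvfft(stats::mvfft(rows) * H, inverse = TRUE)) / L * du_iso
  out <- array(Q[seq_len(d[1]), ], d)
  projection_set(out, projections$angles, projections$times, g)
}

# frequency response (length L >= 2 nu, power of two) of the DC-free
# band-limited ramp at sample spacing du
ramp_response <- function(nu, du, window = "ram-lak") {
  L <- 2^ceiling(log2(2 * nu))
  h <- numeric(L)
  h[1] <- 1 / (4 * du^2)
  n <- seq_len(L / 2)
  odd <- n[n %% 2 == 1]
  h[1 + odd] <- -1 / (pi^2 * odd^2 * du^2)
  h[L + 1 - odd] <- -1 / (pi^2 * odd^2 * du^2)
  H <- Re(stats::fft(h))
  H[1] <- 0                     # remove DC exactly
  if (window == "hann") {
    k <- c(seq(0, L / 2), seq(L / 2 - 1, 1))   # bin distance from DC
    H <- H * 0.5 * (1 + cos(pi * k / (L / 2)))
  }
  H
}

# cosine-weight and ramp-filter a projection stack (the FDK filtering stage)
fdk_filter <- function(projections, window = "ram-lak") {
  g <- projections$geometry
  u <- (seq_len(g$nu) - (g$nu + 1) / 2) * g$du
  v <- (seq_len(g$nv) - (g$nv + 1) / 2) * g$dv
  cosw <- g$sdd / sqrt(g$sdd^2 + outer(u^2, v^2, `+`))
  d <- projections$data * array(cosw, dim(projections$data))
  ramp_filter(projection_set(d, projections$angles, projections$times, g),
              window = window)
}

# per-projection angular weights (half the circular gap, halved again for
# the 360-degree redundancy)
angular_weights <- function(angles) {
  n <- length(angles)
  if (n == 1) return(2 * pi / 2)
  o <- order(angles %% (2 * pi))
  a <- (angles %% (2 * pi))[o]
  gaps <- diff(c(a, a[1] + 2 * pi))
  w <- (gaps + c(gaps[n], gaps[-n])) / 2
  out <- numeric(n)
  out[o] <- w / 2
  out
}

#' FDK reconstruction
#'
#' Feldkamp-Davis-Kress filtered backprojection for a circular full-fan
#' scan: cosine pre-weighting, DC-free Ram-Lak (optionally Hann) ramp
#' filtering of detector rows rescaled to the isocenter, then voxel-driven
#' backprojection with the standard `SID^2 / U^2` distance weight and
#' bilinear detector interpolation, scaled by each projection's angular gap.
#'
#' @param projections a [projection_set()].
#' @param grid a [grid_spec()] for the output volume.
#' @param binning optional [phase_bin()] result; with `bin_label`, only the
#'   projections of that bin are used.
#' @param bin_label 0-based bin to reconstruct (requires `binning`).
#' @param window ramp apodization, `"ram-lak"` or `"hann"`.
#' @return a [cbct_volume()] of attenuation (mm^-1).
#' @export
fdk_reconstruct <- function(projections, grid = grid_spec(), binning = NULL,
                            bin_label = NULL, window = "ram-lak") {
  g <- projections$geometry
  if (!isTRUE(g$full_fan)) stop("half-fan geometry is unsupported")
  filtered <- fdk_filter(projections, window)
  idx <- seq_len(n_projections(projections))
  if (!is.null(binning) && !is.null(bin_label)) {
    idx <- which(binning$bin == bin_label)
    if (length(idx) == 0)
      stop(sprintf("phase bin %d contains no projections", bin_label))
  }
  ang <- projections$angles[idx]
  w <- angular_weights(ang)
  vol <- cpp_backproject(filtered$data[, , idx, drop = FALSE],
                         c(g$nu, g$nv, length(idx)), ang, w,
                         grid$dims, grid$spacing, grid$origin,
                         g$sid, g$sdd, g$du, g$dv, numeric(0))
  cbct_volume(vol, grid$spacing, grid$origin)
}

#' Phase-correlated "4D FDK" reconstruction
#'
#' One FDK volume per phase bin on a common grid (the initial 4D-CBCT).
#'
#' @inheritParams fdk_reconstruct
#' @param binning a [phase_bin()] result of kind `"phase"`.
#' @return a [phase_image_set()] of `n_bins` volumes, ordered by bin index.
#' @export
reconstruct_phase_images <- function(projections, binning,
                                     grid = grid_spec(), window = "ram-lak") {
  if (binning$kind != "phase")
    stop("binning must be of kind 'phase'")
  g <- projections$geometry
  filtered <- fdk_filter(projections, window)
  vols <- lapply(seq_len(binning$n_bins) - 1L, function(b) {
    idx <- which(binning$bin == b)
    if (length(idx) == 0)
      stop(sprintf("phase bin %d contains no projections", b))
    ang <- projections$angles[idx]
    vol <- cpp_backproject(filtered$data[, , idx, drop = FALSE],
                           c(g$nu, g$nv, length(idx)), ang,
                           angular_weights(ang), grid$dims, grid$spacing,
                           grid$origin, g$sid, g$sdd, g$du, g$dv, numeric(0))
    cbct_volume(vol, grid$spacing, grid$origin)
  })
  phase_image_set(vols)
}
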