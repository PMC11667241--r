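#' Landmark set
#'
#' An ordered list of 3D points in physical coordinates (mm), with the grid
#' spacing/origin they refer to. Voxel indices (1-based) are derived on
#' demand.
#'
#' @param points n x 3 matrix of physical coordinates (mm).
#' @param spacing voxel spacing (mm).
#' @param origin world position of voxel (1,1,1) (mm).
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  points <- matrix(points, ncol = 3)
  structure(list(points = points, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set>", nrow(x$points), "points, spacing",
      paste(x$spacing, collapse = " x "), "mm\n")
  invisible(x)
}

#' @export
length.landmark_set <- function(x) nrow(x$points)

#' Read DIR-Lab-style landmark files
#'
#' Whitespace-separated text, one `x y z` triplet of 1-based voxel indices
#' per line. Physical coordinates are `(index - 1) * spacing`.
#'
#' @param path file path.
#' @param spacing voxel spacing (mm) of the volume the indices refer to.
#' @return a [landmark_set()] (empty file gives an empty set).
#' @export
read_dirlab_landmarks <- function(path, spacing) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(landmark_set(matrix(numeric(0), ncol = 3), spacing))
  pts <- matrix(NA_real_, length(lines), 3)
  for (i in seq_along(lines)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != 3 || anyNA(v))
      stop(sprintf("malformed landmark line %d: '%s'", i, lines[i]))
    pts[i, ] <- v
  }
  landmark_set(sweep(pts - 1, 2, spacing, `*`), spacing)
}

#' @rdname read_dirlab_landmarks
#' @param landmarks a [landmark_set()].
#' @param sidecar also write `<path>.json` with the spacing.
#' @export
write_dirlab_landmarks <- function(landmarks, path, sidecar = TRUE) {
  idx <- sweep(landmarks$points, 2, landmarks$spacing, `/`) + 1
  writeLines(apply(idx, 1, function(r)
    paste(sprintf("%.10g", r), collapse = " ")), path)
  if (sidecar)
    jsonlite::write_json(list(spacing = landmarks$spacing,
                              origin = landmarks$origin),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

# trilinear interpolation of a (nx,ny,nz,3) field at continuous 0-based
# voxel coordinates (n x 3 matrix); clamped at borders
interp_field_at_points <- function(dvf, vox0) {
  d <- dim(dvf)[1:3]
  n <- nrow(vox0)
  out <- matrix(0, n, 3)
  cl <- pmin(pmax(vox0, 0), matrix(d - 1, n, 3, byrow = TRUE))
  i0 <- pmin(floor(cl), matrix(pmax(d - 2, 0), n, 3, byrow = TRUE))
  f <- cl - i0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    ii <- pmin(i0[, 1] + dx, d[1] - 1)
    jj <- pmin(i0[, 2] + dy, d[2] - 1)
    kk <- pmin(i0[, 3] + dz, d[3] - 1)
    lin <- 1 + ii + d[1] * (jj + d[2] * kk)
    nvox <- prod(d)
    for (c in 1:3) out[, c] <- out[, c] + wgt * dvf[lin + (c - 1) * nvox]
  }
  out
}

#' Target registration error
#'
#' Per-pair Euclidean distance (mm) between fixed landmarks mapped into the
#' moving frame and the moving landmarks. Without a displacement field the
#' raw fixed points are used (the "before registration" TRE). With one, the
#' pull convention applies: mapped point `= p + D(p)`, `D` interpolated
#' trilinearly at the fixed point.
#'
#' @param fixed,moving [landmark_set()]s of equal length.
#' @param dvf optional displacement array `(nx, ny, nz, 3)`; voxel units by
#'   default (set attribute `units` to `"mm"` for physical fields).
#' @param spacing,origin grid metadata for the field (default from `fixed`).
#' @return list with `mean`, `sd` and `per_point` (mm).
#' @export
compute_tre <- function(fixed, moving, dvf = NULL, spacing = fixed$spacing,
                        origin = fixed$origin) {
  if (length(fixed) != length(moving))
    stop("fixed and moving landmark sets differ in length")
  if (length(fixed) == 0)
    return(list(mean = NaN, sd = NaN, per_point = numeric(0)))
  p <- fixed$points
  if (!is.null(dvf)) {
    d <- dim(dvf)[1:3]
    vox0 <- sweep(sweep(p, 2, origin), 2, spacing, `/`)
    outside <- vox0 < -0.5 | vox0 > matrix(d - 0.5, nrow(p), 3, byrow = TRUE)
    if (any(outside))
      stop(sprintf("landmark %d lies outside the displacement grid",
                   which(apply(outside, 1, any))[1]))
    disp <- interp_field_at_points(dvf, vox0)
    units <- attr(dvf, "units") %||% "voxel"
    if (units == "voxel") disp <- sweep(disp, 2, spacing, `*`)
    p <- p + disp
  }
  dists <- sqrt(rowSums((p - moving$points)^2))
  list(mean = mean(dists), sd = stats::sd(dists), per_point = dists)
}

mask_indices <- function(mask) {
  if (is_cbct_volume(mask)) mask <- mask$data
  idx <- which(mask != 0)
  if (length(idx) == 0) stop("empty ROI mask")
  idx
}

#' Mean-aligned root-mean-square error
#'
#' Shifts the reconstruction by the difference of the ROI means (so a pure
#' intensity offset scores zero), then takes the root-mean-square
#' difference over the ROI. Units follow the inputs (mm^-1 for attenuation
#' volumes).
#'
#' @param recon,gt volumes or arrays on the same grid.
#' @param mask logical/0-1 array (ROI) on the same grid.
#' @return a scalar.
#' @export
rmse_mean_aligned <- function(recon, gt, mask) {
  r <- as_array3(recon); g <- as_array3(gt)
  if (!identical(dim(r), dim(g))) stop("grids differ")
  idx <- mask_indices(mask)
  rv <- r[idx]; gv <- g[idx]
  rv <- rv + (mean(gv) - mean(rv))
  sqrt(mean((rv - gv)^2))
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` over the ROI after the same mean alignment as
#' [rmse_mean_aligned()]; the peak is the ground-truth maximum within the
#' ROI. A perfect match returns `Inf`.
#'
#' @inheritParams rmse_mean_aligned
#' @return PSNR in dB.
#' @export
psnr <- function(recon, gt, mask) {
  idx <- mask_indices(mask)
  g <- as_array3(gt)
  rmse <- rmse_mean_aligned(recon, gt, mask)
  peak <- max(g[idx])
  if (rmse == 0) return(Inf)
  10 * log10(peak^2 / rmse^2)
}

# masked 3D SSIM with a Gaussian window
ssim_masked <- function(a, b, mask_idx, drange, sigma = 1.5) {
  d <- dim(a)
  c1 <- (0.01 * drange)^2
  c2 <- (0.03 * drange)^2
  mu_a <- cpp_gauss3(a, d, sigma)
  mu_b <- cpp_gauss3(b, d, sigma)
  va <- cpp_gauss3(a * a, d, sigma) - mu_a^2
  vb <- cpp_gauss3(b * b, d, sigma) - mu_b^2
  cab <- cpp_gauss3(a * b, d, sigma) - mu_a * mu_b
  map <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(map[mask_idx])
}

#' SSIM with an optimal linear scaling
#'
#' Searches a multiplicative scale `a` on a coarse-to-fine grid (101 points
#' over `[0.2, 5]`, refined once around the best point), with the offset
#' fixed by ROI mean alignment, applies `a * recon + b` and returns the
#' highest masked 3D SSIM (standard constants on the ground-truth dynamic
#' range, Gaussian window).
#'
#' @inheritParams rmse_mean_aligned
#' @param sigma Gaussian window standard deviation (voxels).
#' @return list with `ssim` and `scale`.
#' @export
ssim_optimal_scale <- function(recon, gt, mask, sigma = 1.5) {
  r <- as_array3(recon); g <- as_array3(gt)
  idx <- mask_indices(mask)
  if (stats::sd(g[idx]) == 0) stop("ground truth has zero variance in the ROI")
  drange <- diff(range(g[idx]))
  mg <- mean(g[idx])
  eval_scale <- function(a) {
    ra <- a * r
    ra <- ra + (mg - mean(ra[idx]))
    ssim_masked(ra, g, idx, drange, sigma)
  }
  grid1 <- exp(seq(log(0.2), log(5), length.out = 101))
  s1 <- vapply(grid1, eval_scale, 0)
  best <- grid1[which.max(s1)]
  step <- log(grid1[2]) - log(grid1[1])
  grid2 <- exp(seq(log(best) - step, log(best) + step, length.out = 21))
  s2 <- vapply(grid2, eval_scale, 0)
  k <- which.max(s2)
  list(ssim = s2[k], scale = grid2[k])
}

#' Per-phase, per-ROI evaluation report
#'
#' Computes mean-aligned RMSE, PSNR and scale-searched SSIM for every
#' reconstruction method, phase and ROI against the ground truth, plus TRE
#' when landmarks are supplied. The report is a plain data frame;
#' [write_report()] serializes it deterministically to JSON and TSV.
#'
#' @param recons named list of [phase_image_set()]s (one per method).
#' @param gt a [phase_image_set()] of ground-truth volumes.
#' @param masks named list of ROI arrays.
#' @param landmarks optional `list(fixed =, moving =, dvf =)` forwarded to
#'   [compute_tre()].
#' @return list with `table` (data frame) and optional `tre`.
#' @export
evaluate_pipeline <- function(recons, gt, masks, landmarks = NULL) {
  rows <- list()
  for (m in names(recons)) {
    set <- recons[[m]]
    if (set$n != gt$n) stop("phase counts differ between recon and gt")
    for (ph in seq_len(set$n)) {
      for (roi in names(masks)) {
        r <- set$volumes[[ph]]; g <- gt$volumes[[ph]]
        ss <- ssim_optimal_scale(r, g, masks[[roi]])
        rows[[length(rows) + 1]] <- data.frame(
          method = m, phase = ph, roi = roi,
          rmse = rmse_mean_aligned(r, g, masks[[roi]]),
          psnr = psnr(r, g, masks[[roi]]),
          ssim = ss$ssim)
      }
    }
  }
  out <- list(table = do.call(rbind, rows))
  if (!is.null(landmarks))
    out$tre <- compute_tre(landmarks$fixed, landmarks$moving,
                           landmarks$dvf %||% NULL)
  out
}

#' @rdname evaluate_pipeline
#' @param report an [evaluate_pipeline()] result.
#' @param path_prefix output prefix; writes `<prefix>.json` and
#'   `<prefix>.tsv`.
#' @export
write_report <- function(report, path_prefix) {
  jsonlite::write_json(report, paste0(path_prefix, ".json"), digits = NA,
                       dataframe = "rows", auto_unbox = TRUE)
  utils::write.table(report$table, paste0(path_prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path_prefix)
}
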