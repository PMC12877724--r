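#' Estimate a multiplicative B1 bias field from a b = 0 image
#'
#' A simplified N4-style estimator: in the log domain, alternate between a
#' crude tissue model (1D k-means classification of bias-corrected
#' log-intensities, 3 classes) and extraction of the smooth residual field by
#' mask-normalised Gaussian smoothing. The result is normalised to mean 1
#' inside the mask. Only the contract matters downstream: a smooth positive
#' multiplicative field estimated from the b = 0 image.
#'
#' @param b0 3D array, the non-diffusion-weighted image.
#' @param mask logical 3D array of voxels to use (non-empty).
#' @param grid a [grid_geometry()] (for the smoothing scale in mm).
#' @param smoothing_mm Gaussian smoothing scale of the field, mm.
#' @param iterations alternation count.
#' @param n_classes tissue classes for the piecewise-constant model.
#' @return a `bias_field` object.
#' @export
estimate_bias <- function(b0, mask, grid, smoothing_mm = 40, iterations = 10,
                          n_classes = 3) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  stopifnot(all(dim(b0) == grid$shape), all(dim(mask) == dim(b0)))
  eps <- 1e-6 * max(b0)
  v <- log(pmax(b0, eps))
  sigma_vox <- smoothing_mm / grid$vox_mm
  f <- array(0, dim = dim(b0))
  if (stats::sd(v[mask]) > 1e-12) {
    # accumulate smoothed residuals (N4-style): at the fixed point the
    # smoothed within-class residual vanishes, so re-estimating on
    # corrected data returns a unit field. The tissue model is refreshed
    # each outer iteration; the field accumulates in an inner loop until
    # its increments become negligible.
    for (it in seq_len(iterations)) {
      t_map <- classify_means(v - f, mask, n_classes)
      inc <- smooth_masked(v - f - t_map, mask, sigma_vox)
      if (it > 1 && max(abs(inc[mask])) < 2e-4) break # joint fixed point
      for (inner in 1:50) {
        f <- f + inc
        inc <- smooth_masked(v - f - t_map, mask, sigma_vox)
        if (max(abs(inc[mask])) < 1e-4) break
      }
    }
  }
  f <- f - mean(f[mask])
  field <- exp(f)
  field <- field / mean(field[mask])
  structure(list(grid = grid, field = field), class = "bias_field")
}

# deterministic 1D k-means (quantile init, Lloyd iterations); returns the
# per-voxel class-mean array
classify_means <- function(vol, mask, k) {
  x <- vol[mask]
  centers <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  centers <- unique(centers)
  for (it in 1:15) {
    assign <- max.col(-abs(outer(x, centers, "-")))
    new_centers <- vapply(seq_along(centers), function(c)
      if (any(assign == c)) mean(x[assign == c]) else centers[c], 0)
    if (max(abs(new_centers - centers)) < 1e-10) { centers <- new_centers; break }
    centers <- new_centers
  }
  assign <- max.col(-abs(outer(x, centers, "-")))
  out <- array(0, dim = dim(vol))
  out[mask] <- centers[assign]
  out
}

smooth_masked <- function(vol, mask, sigma_vox) {
  num <- gaussian_smooth3d(vol * mask, sigma_vox)
  den <- gaussian_smooth3d(mask * 1, sigma_vox)
  out <- num / pmax(den, 1e-9)
  out[den < 1e-9] <- 0
  out
}

#' Apply (divide out) a bias field
#'
#' Every volume of the series is divided voxel-wise by the field and the
#' provenance flag is set.
#'
#' @param dwi a [dwi_series()].
#' @param bias a `bias_field`.
#' @return the corrected `dwi_series`.
#' @export
apply_bias <- function(dwi, bias) {
  stop_if_grid_mismatch(dwi$grid, bias$grid, "series and bias field")
  if (any(bias$field <= 0))
    stop("bias field must be strictly positive", call. = FALSE)
  inv <- 1 / bias$field
  for (v in seq_len(dim(dwi$data)[4]))
    dwi$data[, , , v] <- dwi$data[, , , v] * inv
  dwi$bias_corrected <- TRUE
  dwi
}

#' Correct the diffusion signal for background-gradient b-scaling
#'
#' Inverts the forward model S' = S0 (S/S0)^a exactly:
#' S = S0 (S'/S0)^(1/a), applied per voxel and per diffusion-weighted volume
#' using the b = 0 image as the reference; b = 0 volumes pass through.
#' Equivalently the correction is the multiplication
#' S = S' exp(log(S'/S0)(1/a - 1)). Voxels whose S0 falls below
#' 1e-6 x max(S0) are left untouched (they are outside the object or below
#' the noise floor); signals are clamped there before the log.
#'
#' @param dwi a [dwi_series()].
#' @param a a [b_scale_map()] on the same grid.
#' @return corrected `dwi_series` with the provenance flag set.
#' @export
correct_background <- function(dwi, a) {
  stop_if_grid_mismatch(dwi$grid, a$grid, "series and b-scale map")
  if (!dwi$bias_corrected)
    warning("series is not bias-corrected; the b = 0 reference may be biased")
  if (any(a$a <= 0)) stop("b-scale map must be positive", call. = FALSE)
  b0 <- average_b0(dwi)
  eps <- 1e-6 * max(b0)
  valid <- b0 > eps
  logS0 <- log(pmax(b0, eps))
  for (v in dw_index(dwi$scheme)) {
    av <- a$a[, , , v]
    sp <- dwi$data[, , , v]
    corrected <- exp(logS0 + (log(pmax(sp, eps * 1e-6)) - logS0) / av)
    sp[valid] <- corrected[valid]
    dwi$data[, , , v] <- sp
  }
  dwi$background_corrected <- TRUE
  dwi
}

average_b0 <- function(dwi) {
  idx <- which(dwi$scheme$bvals == 0)
  if (length(idx) == 1) return(dwi$data[, , , idx])
  apply(dwi$data[, , , idx, drop = FALSE], 1:3, mean)
}

#' Estimate the Rician noise scale from background voxels
#'
#' In signal-free background the magnitude is Rayleigh distributed with
#' median sigma sqrt(2 ln 2); the estimate is the median background magnitude
#' divided by 1.1774. The in-vivo practice of manually adjusting sigma has no
#' algorithm, so it is exposed as the explicit `override` argument and never
#' applied silently.
#'
#' @param dwi a [dwi_series()].
#' @param background_mask logical 3D array; NULL selects voxels below 10% of
#'   the 99th percentile of the mean image (outside the head).
#' @param min_voxels minimum background size.
#' @param override if non-NULL, returned as-is (manual adjustment).
#' @return noise sigma in signal units.
#' @export
estimate_noise_sigma <- function(dwi, background_mask = NULL,
                                 min_voxels = 500, override = NULL) {
  if (!is.null(override)) return(override)
  if (is.null(background_mask)) {
    mean_img <- apply(dwi$data, 1:3, mean)
    thr <- 0.2 * stats::quantile(mean_img, 0.99, names = FALSE)
    background_mask <- mean_img < thr
  }
  if (sum(background_mask) < min_voxels)
    stop(sprintf("background region too small (%d < %d voxels)",
                 sum(background_mask), min_voxels), call. = FALSE)
  vals <- as.vector(dwi$data[rep_len(as.vector(background_mask),
                                     length(dwi$data))])
  stats::median(vals) / sqrt(2 * log(2))
}
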