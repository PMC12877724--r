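#' Grid geometry
#'
#' A light container for a regular 3D voxel grid: integer shape, isotropic
#' voxel size in mm, and a voxel-to-world affine in RAS+ orientation. Voxel
#' centres sit at integer indices, 0-based; by default the grid centre maps to
#' the world origin (scanner isocentre).
#'
#' @param shape integer length-3 vector of voxel counts.
#' @param vox_mm isotropic voxel size in mm.
#' @param origin optional world position (mm) of voxel (0,0,0); default places
#'   the grid centre at the origin.
#' @return an object of class `grid_geometry` with fields `shape`, `vox_mm`
#'   and `affine` (4x4 voxel-to-world matrix).
#' @export
grid_geometry <- function(shape, vox_mm = 3, origin = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), vox_mm > 0)
  if (is.null(origin)) origin <- -(shape - 1) / 2 * vox_mm
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(rep(vox_mm, 3))
  affine[1:3, 4] <- origin
  structure(list(shape = shape, vox_mm = vox_mm, affine = affine),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid %dx%dx%d, voxel %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3], x$vox_mm))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) && max(abs(a$affine - b$affine)) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch between %s", what), call. = FALSE)
}

#' Voxel-to-world and world-to-voxel coordinate transforms
#'
#' Voxel indices are 0-based and continuous; world coordinates are mm.
#'
#' @param grid a [grid_geometry()].
#' @param ijk,xyz n x 3 matrices (or length-3 vectors) of coordinates.
#' @return n x 3 matrix of transformed coordinates.
#' @export
vox2world <- function(grid, ijk) {
  ijk <- rbind3(ijk)
  t(grid$affine[1:3, 1:3] %*% t(ijk) + grid$affine[1:3, 4])
}

#' @rdname vox2world
#' @export
world2vox <- function(grid, xyz) {
  xyz <- rbind3(xyz)
  t(solve(grid$affine[1:3, 1:3], t(xyz) - grid$affine[1:3, 4]))
}

rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

# World coordinates (mm) of every voxel centre, as three arrays of the grid
# shape. Used for analytic phantom geometry and field models.
coordinate_arrays <- function(grid) {
  s <- grid$shape
  i <- array(rep(0:(s[1] - 1), times = s[2] * s[3]), dim = s)
  j <- array(rep(rep(0:(s[2] - 1), each = s[1]), times = s[3]), dim = s)
  k <- array(rep(0:(s[3] - 1), each = s[1] * s[2]), dim = s)
  A <- grid$affine
  list(x = A[1, 1] * i + A[1, 2] * j + A[1, 3] * k + A[1, 4],
       y = A[2, 1] * i + A[2, 2] * j + A[2, 3] * k + A[2, 4],
       z = A[3, 1] * i + A[3, 2] * j + A[3, 3] * k + A[3, 4])
}

#' Trilinear interpolation of a 3D array at continuous voxel coordinates
#'
#' @param vol 3D array.
#' @param ijk n x 3 matrix of continuous 0-based voxel coordinates.
#' @param outside value returned outside the grid (default 0).
#' @return numeric vector of length n.
#' @export
interp_trilinear <- function(vol, ijk, outside = 0) {
  ijk <- rbind3(ijk)
  d <- dim(vol)
  n <- nrow(ijk)
  out <- rep(outside, n)
  inside <- ijk[, 1] >= 0 & ijk[, 1] <= d[1] - 1 &
            ijk[, 2] >= 0 & ijk[, 2] <= d[2] - 1 &
            ijk[, 3] >= 0 & ijk[, 3] <= d[3] - 1
  if (!any(inside)) return(out)
  p <- ijk[inside, , drop = FALSE]
  i0 <- pmin(floor(p[, 1]), d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(p[, 2]), d[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(p[, 3]), d[3] - 2); k0 <- pmax(k0, 0)
  fx <- p[, 1] - i0; fy <- p[, 2] - j0; fz <- p[, 3] - k0
  idx <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  v000 <- vol[idx(i0, j0, k0)];         v100 <- vol[idx(i0 + 1, j0, k0)]
  v010 <- vol[idx(i0, j0 + 1, k0)];     v110 <- vol[idx(i0 + 1, j0 + 1, k0)]
  v001 <- vol[idx(i0, j0, k0 + 1)];     v101 <- vol[idx(i0 + 1, j0, k0 + 1)]
  v011 <- vol[idx(i0, j0 + 1, k0 + 1)]; v111 <- vol[idx(i0 + 1, j0 + 1, k0 + 1)]
  out[inside] <-
    (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
                fy * ((1 - fx) * v010 + fx * v110)) +
    fz * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
          fy * ((1 - fx) * v011 + fx * v111))
  out
}

# Separable Gaussian smoothing of a 3D array, sigma in voxels (recycled to 3).
# Truncated at 3 sigma; kernel renormalised, reflecting boundaries.
gaussian_smooth3d <- function(vol, sigma) {
  sigma <- rep(sigma, length.out = 3)
  out <- vol
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

convolve_axis <- function(vol, kernel, axis) {
  d <- dim(vol)
  if (length(kernel) == 1) return(vol * kernel)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  dm <- dim(v)
  m <- matrix(v, nrow = dm[1])
  n <- dm[1]
  r <- (length(kernel) - 1L) / 2L
  # reflect-pad along the filtered axis (clamp when the axis is shorter than r)
  if (r < n) {
    idx_pre <- (r + 1):2
    idx_post <- (n - 1):(n - r)
  } else {
    idx_pre <- pmax(1L, pmin(n, (r + 1):2))
    idx_post <- pmax(1L, pmin(n, (n - 1):(n - r)))
  }
  mp <- rbind(m[idx_pre, , drop = FALSE], m, m[idx_post, , drop = FALSE])
  res <- matrix(0, nrow = n, ncol = ncol(m))
  for (t in seq_along(kernel))
    res <- res + kernel[t] * mp[(t - 1) + seq_len(n), , drop = FALSE]
  v <- array(res, dim = dm)
  aperm(v, order(perm))
}

# Deterministic substream seed from a global seed and a stage name.
# Keeps results order-independent across stages; value < 2^31.
derive_seed <- function(global_seed, name) {
  h <- as.double(global_seed) %% 2147483647
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

unit_rows <- function(m, tol = 1e-12) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm < tol] <- 1
  m / nrm
}
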