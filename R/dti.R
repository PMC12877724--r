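#' Diffusion tensor estimation and scalar maps
#'
#' The tensor model is ln S = ln S0 - b u' D u per volume; fitting is
#' log-linear weighted least squares (weights = squared predicted signals,
#' two passes) or the robust RESTORE scheme (iteratively reweighted with
#' Geman-McClure weights, outlier exclusion at C sigma, and a final refit on
#' the retained volumes).
#'
#' @name dti
NULL

# design matrix for ln S = X [lnS0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz]
dti_design <- function(scheme) {
  b <- scheme$bvals; u <- scheme$dirs
  cbind(1,
        -b * u[, 1]^2, -b * u[, 2]^2, -b * u[, 3]^2,
        -2 * b * u[, 1] * u[, 2], -2 * b * u[, 1] * u[, 3],
        -2 * b * u[, 2] * u[, 3])
}

check_dti_design <- function(X, scheme) {
  if (sum(scheme$bvals > 0) < 6 || qr(X)$rank < 7)
    stop("tensor fit needs at least 6 non-collinear diffusion directions plus a b = 0 volume",
         call. = FALSE)
  invisible(TRUE)
}

#' Fit diffusion tensors by two-pass weighted least squares
#'
#' @param dwi a [dwi_series()].
#' @param mask logical 3D array of voxels to fit; NULL fits voxels whose
#'   b = 0 signal exceeds 5% of its maximum.
#' @return object of class `tensor_field` with per-voxel tensor elements
#'   (`d`, order xx yy zz xy xz yz, mm^2/s), `log_s0`, eigenvalues `evals`
#'   (descending), principal eigenvector `e1`, fit-validity mask and
#'   per-voxel excluded-volume counts (zero for plain WLS).
#' @export
fit_dti_wls <- function(dwi, mask = NULL) {
  X <- dti_design(dwi$scheme)
  check_dti_design(X, dwi$scheme)
  if (is.null(mask)) {
    b0 <- average_b0(dwi)
    mask <- b0 > 0.05 * max(b0)
  }
  idx <- which(mask)
  nv <- dim(dwi$data)[4]
  Y <- log(pmax(matrix(dwi$data, ncol = nv)[idx, , drop = FALSE],
                1e-6 * max(dwi$data)))
  # pass 1: OLS for all voxels at once
  beta <- t(solve(crossprod(X), crossprod(X, t(Y))))
  # pass 2: per-voxel WLS with weights = squared predicted signals
  for (i in seq_along(idx)) {
    w <- exp(2 * drop(X %*% beta[i, ]))
    XtW <- t(X * w)
    beta[i, ] <- solve(XtW %*% X, XtW %*% Y[i, ])
  }
  tensor_field_from_beta(dwi$grid, mask, beta,
                         n_excluded = integer(length(idx)),
                         valid = rep(TRUE, length(idx)))
}

tensor_field_from_beta <- function(grid, mask, beta, n_excluded, valid) {
  s <- grid$shape
  idx <- which(mask)
  put <- function(vals, ncol) {
    a <- array(0, dim = c(prod(s), ncol))
    a[idx, ] <- vals
    array(a, dim = c(s, ncol))
  }
  d <- beta[, 2:7, drop = FALSE]
  es <- eigen_symmetric3(d)
  structure(list(grid = grid, mask = mask,
                 d = put(d, 6),
                 log_s0 = array(put(beta[, 1, drop = FALSE], 1), dim = s),
                 evals = put(es$evals, 3),
                 e1 = put(es$e1, 3),
                 n_excluded = array(put(matrix(n_excluded), 1), dim = s),
                 valid_fit = array(put(matrix(valid), 1) > 0, dim = s)),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("tensor field: %d fitted voxels, %d invalid\n",
              sum(x$mask), sum(x$mask) - sum(x$valid_fit)))
  invisible(x)
}

# vectorised eigen-decomposition of symmetric 3x3 tensors given as rows
# (xx, yy, zz, xy, xz, yz); returns descending eigenvalues and the principal
# eigenvector
eigen_symmetric3 <- function(d) {
  xx <- d[, 1]; yy <- d[, 2]; zz <- d[, 3]
  xy <- d[, 4]; xz <- d[, 5]; yz <- d[, 6]
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * (xy^2 + xz^2 + yz^2)
  p <- sqrt(pmax(p2, 0) / 6)
  n <- length(xx)
  l1 <- l2 <- l3 <- q
  nz <- p > 0
  if (any(nz)) {
    bxx <- (xx - q) / p; byy <- (yy - q) / p; bzz <- (zz - q) / p
    bxy <- xy / p; bxz <- xz / p; byz <- yz / p
    detb <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- (q + 2 * p * cos(phi))[nz]
    l3[nz] <- (q + 2 * p * cos(phi + 2 * pi / 3))[nz]
    l2 <- 3 * q - l1 - l3
  }
  # principal eigenvector from the largest column of (A - l2 I)(A - l3 I)
  e1 <- matrix(0, n, 3)
  if (any(nz)) {
    a1 <- xx - l2; a2 <- yy - l2; a3 <- zz - l2
    c1 <- xx - l3; c2 <- yy - l3; c3 <- zz - l3
    m11 <- a1 * c1 + xy * xy + xz * xz
    m21 <- xy * c1 + a2 * xy + yz * xz
    m31 <- xz * c1 + yz * xy + a3 * xz
    m12 <- a1 * xy + xy * c2 + xz * yz
    m22 <- xy * xy + a2 * c2 + yz * yz
    m32 <- xz * xy + yz * c2 + a3 * yz
    m13 <- a1 * xz + xy * yz + xz * c3
    m23 <- xy * xz + a2 * yz + yz * c3
    m33 <- xz * xz + yz * yz + a3 * c3
    n1 <- m11^2 + m21^2 + m31^2
    n2 <- m12^2 + m22^2 + m32^2
    n3 <- m13^2 + m23^2 + m33^2
    pick2 <- n2 >= n1 & n2 >= n3
    pick3 <- n3 > n1 & n3 > n2 & !pick2
    ex <- m11; ey <- m21; ez <- m31
    ex[pick2] <- m12[pick2]; ey[pick2] <- m22[pick2]; ez[pick2] <- m32[pick2]
    ex[pick3] <- m13[pick3]; ey[pick3] <- m23[pick3]; ez[pick3] <- m33[pick3]
    nrm <- sqrt(ex^2 + ey^2 + ez^2)
    ok <- nz & nrm > 1e-12
    e1[ok, ] <- cbind(ex, ey, ez)[ok, , drop = FALSE] / nrm[ok]
  }
  list(evals = unname(cbind(l1, l2, l3)), e1 = e1)
}

# FA / MD from tensor rows; voxels outside `pos` get zeros
eigen_scalar_maps <- function(d, pos = rep(TRUE, nrow(d))) {
  es <- eigen_symmetric3(d)
  lam <- es$evals
  md <- rowMeans(lam)
  num <- (lam[, 1] - md)^2 + (lam[, 2] - md)^2 + (lam[, 3] - md)^2
  den <- lam[, 1]^2 + lam[, 2]^2 + lam[, 3]^2
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  fa[!pos] <- 0; md[!pos] <- 0
  list(fa = fa, md = md, e1 = es$e1, evals = lam)
}

#' Robust tensor fit (RESTORE)
#'
#' Iteratively reweighted fit with Geman-McClure weights on signal-domain
#' residuals scaled by the noise sigma; volumes whose final residual exceeds
#' `c_outlier` sigma are excluded and the tensor refitted on the retained
#' volumes. Voxels retaining fewer than 7 volumes (6 directions + b = 0) are
#' flagged invalid rather than silently fitted.
#'
#' @inheritParams fit_dti_wls
#' @param sigma noise standard deviation in signal units (> 0).
#' @param c_outlier outlier threshold in sigma units.
#' @param max_iter IRLS iteration cap.
#' @param tol relative parameter-change convergence tolerance.
#' @return a `tensor_field`; `n_excluded` holds per-voxel exclusion counts.
#' @export
fit_dti_restore <- function(dwi, sigma, mask = NULL, c_outlier = 3,
                            max_iter = 20, tol = 1e-6) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  X <- dti_design(dwi$scheme)
  check_dti_design(X, dwi$scheme)
  if (is.null(mask)) {
    b0 <- average_b0(dwi)
    mask <- b0 > 0.05 * max(b0)
  }
  idx <- which(mask)
  nv <- dim(dwi$data)[4]
  S <- matrix(dwi$data, ncol = nv)[idx, , drop = FALSE]
  Y <- log(pmax(S, 1e-6 * max(dwi$data)))
  beta <- t(solve(crossprod(X), crossprod(X, t(Y))))
  n_excl <- integer(length(idx))
  valid <- rep(TRUE, length(idx))
  for (i in seq_along(idx)) {
    bi <- beta[i, ]
    for (it in seq_len(max_iter)) {
      shat <- exp(drop(X %*% bi))
      r <- S[i, ] - shat
      w_rob <- 1 / (1 + (r / (c_outlier * sigma))^2)^2
      w <- shat^2 * w_rob
      XtW <- t(X * w)
      bnew <- tryCatch(solve(XtW %*% X, XtW %*% Y[i, ]),
                       error = function(e) bi)
      if (max(abs(bnew - bi)) <= tol * max(abs(bi), 1e-12)) { bi <- bnew; break }
      bi <- bnew
    }
    shat <- exp(drop(X %*% bi))
    out <- abs(S[i, ] - shat) > c_outlier * sigma
    n_excl[i] <- sum(out)
    if (any(out)) {
      keep <- !out
      if (sum(keep) < 7 || qr(X[keep, , drop = FALSE])$rank < 7) {
        valid[i] <- FALSE
        beta[i, ] <- bi
        next
      }
      Xk <- X[keep, , drop = FALSE]
      bk <- solve(crossprod(Xk), crossprod(Xk, Y[i, keep]))
      for (p2 in 1:2) {
        w <- exp(2 * drop(Xk %*% bk))
        XtW <- t(Xk * w)
        bk <- solve(XtW %*% Xk, XtW %*% Y[i, keep])
      }
      beta[i, ] <- bk
    } else beta[i, ] <- bi
  }
  tensor_field_from_beta(dwi$grid, mask, beta, n_excl, valid)
}

#' Scalar maps from a tensor field
#'
#' FA = sqrt(3/2) ||lambda - mean|| / ||lambda||, MD = mean eigenvalue, and
#' the direction-encoded colour map DEC = |e1| x FA per RGB channel.
#' Negative eigenvalues (possible in noisy fits) are retained, not clipped.
#'
#' @param tensor a `tensor_field`.
#' @return list of arrays `fa` (dimensionless), `md` (mm^2/s), `dec`
#'   (shape x 3, in [0, 1]).
#' @export
tensor_scalars <- function(tensor) {
  s <- tensor$grid$shape
  lam <- matrix(tensor$evals, ncol = 3)
  md <- rowMeans(lam)
  num <- rowSums((lam - md)^2)
  den <- rowSums(lam^2)
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  fa <- pmin(fa, 1)
  e1 <- matrix(tensor$e1, ncol = 3)
  dec <- abs(e1) * fa
  list(fa = array(fa, dim = s), md = array(md, dim = s),
       dec = array(dec, dim = c(s, 3)))
}
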