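#' @title Diffusion gradient schemes and PGSE arithmetic
#' @name scheme
#' @details
#' b-values are in s/mm^2, gradient amplitudes in mT/m, times in ms at every
#' interface; conversion to SI happens internally. The gyromagnetic ratio of
#' the proton is fixed at 2.6752219e8 rad s^-1 T^-1.
NULL

GAMMA_H <- 2.6752219e8 # rad s^-1 T^-1

#' PGSE b-value for rectangular monopolar gradient lobes
#'
#' `pgse_b()` evaluates b = gamma^2 G^2 delta^2 (Delta - delta/3);
#' `gradient_for_b()` inverts it for the gradient amplitude.
#'
#' @param G gradient amplitude, mT/m.
#' @param b target b-value, s/mm^2.
#' @param delta lobe duration, ms.
#' @param Delta lobe separation (leading edge to leading edge), ms.
#' @return b in s/mm^2, or G in mT/m.
#' @export
pgse_b <- function(G, delta, Delta) {
  check_pgse_timing(delta, Delta)
  stopifnot(all(G >= 0))
  d <- delta * 1e-3; D <- Delta * 1e-3
  b_si <- GAMMA_H^2 * (G * 1e-3)^2 * d^2 * (D - d / 3) # s/m^2
  b_si * 1e-6
}

#' @rdname pgse_b
#' @export
gradient_for_b <- function(b, delta, Delta) {
  check_pgse_timing(delta, Delta)
  stopifnot(all(b >= 0))
  d <- delta * 1e-3; D <- Delta * 1e-3
  sqrt(b * 1e6 / (GAMMA_H^2 * d^2 * (D - d / 3))) * 1e3
}

check_pgse_timing <- function(delta, Delta) {
  if (any(delta <= 0) || any(Delta <= 0))
    stop("PGSE timings must be positive", call. = FALSE)
  if (any(delta >= Delta))
    stop("PGSE requires delta < Delta", call. = FALSE)
  invisible(TRUE)
}

#' Construct a gradient scheme
#'
#' @param bvals numeric vector of per-volume b-values (s/mm^2).
#' @param dirs n x 3 matrix of encoding directions in the image-axis frame;
#'   rows with b = 0 may be zero vectors. Non-unit rows are renormalised.
#' @param groups optional integer group label per volume (NA for b = 0);
#'   groups partition the diffusion-weighted volumes.
#' @param delta,Delta PGSE lobe duration and separation, ms.
#' @param te effective echo time, ms (used by timing-aware b-scaling models).
#' @return object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(bvals, dirs, groups = NULL,
                            delta = 35, Delta = 42, te = 84) {
  check_pgse_timing(delta, Delta)
  dirs <- rbind3(dirs)
  stopifnot(length(bvals) == nrow(dirs), all(bvals >= 0))
  dw <- bvals > 0
  if (any(dw)) {
    nrm <- sqrt(rowSums(dirs[dw, , drop = FALSE]^2))
    if (any(nrm < 1e-6))
      stop("zero direction vector on a diffusion-weighted volume", call. = FALSE)
    dirs[dw, ] <- dirs[dw, , drop = FALSE] / nrm
  }
  dirs[!dw, ] <- 0
  if (is.null(groups)) groups <- ifelse(dw, 1L, NA_integer_)
  stopifnot(length(groups) == length(bvals))
  G <- if (any(dw)) gradient_for_b(max(bvals), delta, Delta) else 0
  structure(list(bvals = as.numeric(bvals), dirs = dirs,
                 groups = as.integer(groups),
                 delta = delta, Delta = Delta, te = te,
                 G = G, gamma = GAMMA_H),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf(
    "gradient scheme: %d volumes (%d b=0), b max %.0f s/mm^2, G %.2f mT/m, delta %g ms, Delta %g ms\n",
    length(x$bvals), sum(x$bvals == 0), max(x$bvals), x$G, x$delta, x$Delta))
  invisible(x)
}

n_volumes <- function(scheme) length(scheme$bvals)
dw_index <- function(scheme) which(scheme$bvals > 0)

#' Electrostatically arranged diffusion directions
#'
#' Minimises the Coulomb energy sum over 1/||di - dj|| and 1/||di + dj||
#' (antipodal pairs included, so the result is a set of axes) by projected
#' gradient descent on the sphere with backtracking, plus the same energy
#' evaluated within each group, so that each group is separately well spread
#' and an early-terminated scan still carries a usable subset.
#'
#' @param n number of directions.
#' @param n_groups number of interleaved groups; must divide `n`.
#' @param iterations descent iterations per restart.
#' @param restarts random restarts; the lowest-energy result is kept.
#' @param seed RNG seed.
#' @return list with `dirs` (n x 3 unit rows), `groups` (integer labels) and
#'   `energy` (final total energy).
#' @export
electrostatic_directions <- function(n, n_groups = 1, iterations = 1000,
                                     restarts = 10, seed = 1) {
  stopifnot(n >= 1, n_groups >= 1)
  if (n %% n_groups != 0)
    stop("n directions must be divisible by n groups", call. = FALSE)
  groups <- rep(seq_len(n_groups), each = n / n_groups)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      x <- unit_rows(matrix(stats::rnorm(n * 3), ncol = 3))
      res <- descend_electrostatic(x, groups, iterations)
      if (is.null(best) || res$energy < best$energy) best <- res
    }
  })
  list(dirs = best$x, groups = groups, energy = best$energy)
}

coulomb_energy_grad <- function(x) {
  n <- nrow(x)
  if (n < 2) return(list(energy = 0, grad = matrix(0, n, 3)))
  G <- tcrossprod(x) # unit rows: |xi-xj|^2 = 2-2G, |xi+xj|^2 = 2+2G
  rm <- sqrt(pmax(2 - 2 * G, 1e-18)); diag(rm) <- Inf
  rp <- sqrt(pmax(2 + 2 * G, 1e-18)); diag(rp) <- Inf
  e <- sum(1 / rm[upper.tri(rm)] + 1 / rp[upper.tri(rp)])
  wm <- 1 / rm^3; wp <- 1 / rp^3
  # d/dxi sum_j 1/|xi-xj| = -sum_j (xi-xj)/|xi-xj|^3, likewise for the + term
  g <- -(x * rowSums(wm) - wm %*% x) - (x * rowSums(wp) + wp %*% x)
  list(energy = e, grad = g)
}

total_energy_grad <- function(x, groups) {
  res <- coulomb_energy_grad(x)
  e <- res$energy; g <- res$grad
  if (max(groups) > 1) {
    for (gr in unique(groups)) {
      idx <- which(groups == gr)
      sub <- coulomb_energy_grad(x[idx, , drop = FALSE])
      e <- e + sub$energy
      g[idx, ] <- g[idx, ] + sub$grad
    }
  }
  list(energy = e, grad = g)
}

descend_electrostatic <- function(x, groups, iterations) {
  cur <- total_energy_grad(x, groups)
  step <- 0.05
  for (it in seq_len(iterations)) {
    cand <- unit_rows(x - step * cur$grad)
    new <- total_energy_grad(cand, groups)
    if (new$energy < cur$energy) {
      x <- cand; cur <- new; step <- step * 1.2
    } else {
      step <- step / 2
      if (step < 1e-12) break
    }
  }
  list(x = x, energy = cur$energy)
}

#' The default ultra-low-field diffusion protocol scheme
#'
#' One b = 0 volume plus `n` directions at b = 945 s/mm^2, arranged by
#' electrostatic repulsion into `n_groups` separately well-spread groups,
#' with monopolar PGSE timings delta = 35 ms, Delta = 42 ms and effective
#' echo time 84 ms.
#'
#' @param n_dirs diffusion-weighted direction count.
#' @param n_groups direction groups (early-termination subsets).
#' @param b b-value at isocentre, s/mm^2.
#' @inheritParams gradient_scheme
#' @param n_b0 number of b = 0 volumes (placed first).
#' @param seed seed for the direction optimiser.
#' @param iterations,restarts passed to [electrostatic_directions()].
#' @return a `gradient_scheme`.
#' @export
ulf_scheme <- function(n_dirs = 18, n_groups = 3, b = 945,
                       delta = 35, Delta = 42, te = 84, n_b0 = 1,
                       seed = 1, iterations = 1000, restarts = 10) {
  es <- electrostatic_directions(n_dirs, n_groups, iterations, restarts, seed)
  bvals <- c(rep(0, n_b0), rep(b, n_dirs))
  dirs <- rbind(matrix(0, n_b0, 3), es$dirs)
  groups <- c(rep(NA_integer_, n_b0), es$groups)
  gradient_scheme(bvals, dirs, groups, delta, Delta, te)
}

#' Rotate b-vectors under an affine transform
#'
#' Extracts the rotation component of the affine's 3x3 linear part by polar
#' decomposition and applies it to every encoding direction; b-values and
#' zero vectors are unchanged.
#'
#' @param affine 4x4 (or 3x3) matrix with invertible linear part.
#' @param scheme a `gradient_scheme`.
#' @return the rotated `gradient_scheme`.
#' @export
rotate_bvecs <- function(affine, scheme) {
  A <- as.matrix(affine)
  L <- if (all(dim(A) == 4)) A[1:3, 1:3] else A
  stopifnot(all(dim(L) == 3))
  if (abs(det(L)) < 1e-12)
    stop("affine linear part is singular", call. = FALSE)
  sv <- svd(L)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  dw <- scheme$bvals > 0
  scheme$dirs[dw, ] <- t(R %*% t(scheme$dirs[dw, , drop = FALSE]))
  scheme
}

#' Scan time accounting for a multi-shot acquisition
#'
#' @param shots phase-encode shots per volume.
#' @param tr_ms repetition time, ms.
#' @param n_volumes number of volumes.
#' @param round_seconds round to the nearest integer second for reporting.
#' @return acquisition time in seconds.
#' @export
scan_time <- function(shots, tr_ms, n_volumes = 1, round_seconds = FALSE) {
  stopifnot(shots >= 0, tr_ms >= 0, n_volumes >= 0)
  s <- shots * tr_ms * n_volumes / 1000
  if (round_seconds) round(s) else s
}
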