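# Shared fixtures, built once per test run. Small grids keep the suite fast;
# the geometry is the default phantom scaled down.

fixture_env <- new.env()

small_phantom <- function() {
  if (is.null(fixture_env$phantom))
    fixture_env$phantom <- default_phantom(n = 32, vox_mm = 3)
  fixture_env$phantom
}

small_scheme <- function() {
  if (is.null(fixture_env$scheme))
    fixture_env$scheme <- ulf_scheme(seed = 1, iterations = 300, restarts = 3)
  fixture_env$scheme
}

clean_dwi <- function() {
  if (is.null(fixture_env$dwi))
    fixture_env$dwi <- simulate_dwi(small_phantom(), small_scheme(), s0 = 100)
  fixture_env$dwi
}

wm_response <- function() {
  if (is.null(fixture_env$resp))
    fixture_env$resp <- estimate_response(clean_dwi())
  fixture_env$resp
}

# masks of analytically pure voxel populations on the small phantom
pure_single_fibre <- function(ph = small_phantom()) {
  ph$bundle_masks$cyl_x & ph$comp_frac[, , , 1] > 0.999 & ph$wm > 0.999 &
    ph$gm < 1e-9 & ph$csf < 1e-9
}

balanced_crossing <- function(ph = small_phantom()) {
  ph$bundle_masks$cyl_x & ph$bundle_masks$cyl_y & ph$wm > 0.999 &
    apply(ph$comp_frac, 1:3, min) > 0.45
}

# single-tensor series on a uniform grid: every voxel carries tensor D
# (given as eigenvalues + axis), no partial volumes, optional per-volume
# b-scaling; handy for closed-form checks
uniform_tensor_dwi <- function(scheme, evals = c(1.7e-3, 2e-4, 2e-4),
                               axis = c(1, 0, 0), n = 8, s0 = 100,
                               a = 1) {
  grid <- grid_geometry(rep(n, 3), 3)
  axis <- axis / sqrt(sum(axis^2))
  lam_perp <- mean(evals[2:3])
  sig <- vapply(seq_along(scheme$bvals), function(v) {
    b <- scheme$bvals[v]
    if (b == 0) return(s0)
    u <- scheme$dirs[v, ]
    adc <- lam_perp + (evals[1] - lam_perp) * sum(u * axis)^2
    av <- if (length(a) == 1) a else a[v]
    s0 * exp(-av * b * adc)
  }, 0)
  data <- array(rep(sig, each = n^3), dim = c(rep(n, 3), length(sig)))
  dwi_series(data, grid, scheme)
}

expect_angle_le <- function(v1, v2, deg) {
  ang <- acos(min(1, abs(sum(v1 * v2) /
                           sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  expect_lte(ang, deg)
}
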