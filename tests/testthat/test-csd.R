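test_that("the SH basis is orthonormal and matches reference Legendre", {
  expect_equal(ncol(sh_basis(4, fibonacci_axes(10))), 15)
  expect_equal(ncol(sh_basis(8, fibonacci_axes(10))), 45)
  expect_error(sh_basis(3, fibonacci_axes(10)), "even")
  # l = 0 column is the constant 1/sqrt(4 pi)
  B <- sh_basis(4, fibonacci_axes(5000))
  expect_equal(unique(round(B[, 1], 12)), round(1 / sqrt(4 * pi), 12))
  # numerical orthonormality on a quasi-uniform set
  G <- crossprod(B) * 4 * pi / 5000
  expect_lt(max(abs(G - diag(15))), 1e-2)
  # associated Legendre against the independent pracma implementation
  skip_if_not_installed("pracma")
  for (x in c(-0.7, 0, 0.3, 0.95)) {
    expect_equal(drop(ulfdwi:::assoc_legendre(4, x)),
                 drop(pracma::legendre(4, x)), tolerance = 1e-12)
    expect_equal(drop(ulfdwi:::assoc_legendre(2, x)),
                 drop(pracma::legendre(2, x)), tolerance = 1e-12)
  }
})

test_that("response estimation reproduces the single-fibre profile", {
  resp <- wm_response()
  expect_equal(resp$tissue, "wm")
  expect_equal(length(resp$coef[[2]]), 3) # lmax 4 zonal: l = 0, 2, 4
  expect_gt(resp$coef[[1]][1], 0)
  # projection residual on a clean single-fibre population: the zonal model
  # reproduces the reoriented signal profile at the truncation floor
  sch <- small_scheme()
  clean <- uniform_tensor_dwi(sch, axis = c(0, 0, 1), n = 8)
  rc <- estimate_response(clean, min_voxels = 20)
  ct <- seq(0, 1, length.out = 200)
  true_sig <- exp(-945 * (2e-4 + (1.7e-3 - 2e-4) * ct^2))
  pred <- drop(ulfdwi:::zonal_basis(4, ct) %*% rc$coef[[2]])
  expect_lt(sqrt(mean((pred - true_sig)^2)) / mean(true_sig), 0.01)
  # too few voxels is an error
  ph <- small_phantom()
  tiny <- array(FALSE, ph$grid$shape)
  tiny[which(pure_single_fibre(ph))[1:10]] <- TRUE
  expect_error(estimate_response(clean_dwi(), mask = tiny), "selected")
})

test_that("response zonal coefficients are rotation-invariant", {
  th <- 40 * pi / 180
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  sch <- small_scheme()
  d0 <- uniform_tensor_dwi(sch, axis = c(0, 0, 1), n = 8)
  d1 <- uniform_tensor_dwi(rotate_bvecs(R, sch), axis = drop(R %*% c(0, 0, 1)),
                           n = 8)
  r0 <- estimate_response(d0, min_voxels = 20)
  r1 <- estimate_response(d1, min_voxels = 20)
  expect_equal(r1$coef[[2]], r0$coef[[2]], tolerance = 1e-6)
})

test_that("CSD recovers single fibres, crossings and tissue fractions", {
  ph <- small_phantom()
  dwi <- clean_dwi()
  resp <- wm_response()
  pure <- pure_single_fibre(ph)
  cx <- balanced_crossing(ph)
  fod <- csd_fit(dwi, resp, mask = pure | cx)
  # noiseless single-fibre: global peak within 5 degrees of the x axis
  pk <- fod_peaks(fod, mask = pure)
  expect_true(all(pk$n_peaks == 1))
  for (i in seq_along(pk$index))
    expect_angle_le(pk$peaks[i, , 1], c(1, 0, 0), 5)
  # 90-degree crossing resolved into two peaks within 10 degrees
  pk2 <- fod_peaks(fod, mask = cx)
  expect_true(all(pk2$n_peaks == 2))
  for (i in seq_along(pk2$index)) {
    errs <- sapply(list(c(1, 0, 0), c(0, 1, 0)), function(ax) {
      min(acos(pmin(1, abs(c(sum(pk2$peaks[i, , 1] * ax),
                             sum(pk2$peaks[i, , 2] * ax))))) * 180 / pi)
    })
    expect_lt(max(errs), 10)
  }
  # soft non-negativity contract on the constraint set
  Ac <- sh_basis(4, constraint_directions())
  amp <- matrix(fod$coef, ncol = 15)[which(pure | cx), ] %*% t(Ac)
  expect_gte(min(amp), -0.01 * max(amp))
  # CSD peak agrees with the tensor principal eigenvector
  tf <- fit_dti_wls(dwi, mask = pure)
  e1 <- matrix(tf$e1, ncol = 3)[which(pure), ]
  for (i in seq_along(pk$index))
    expect_angle_le(pk$peaks[i, , 1], e1[i, ], 2)
})

test_that("two-tissue CSD separates WM from CSF", {
  ph <- small_phantom()
  dwi <- clean_dwi()
  resp <- wm_response()
  cresp <- estimate_response(dwi, mask = ph$csf > 0.99, tissue = "csf")
  # pure CSF: WM fODF collapses, CSF fraction 1
  csfm <- ph$csf > 0.99
  fodc <- csd_fit(dwi, resp, csf_response = cresp, mask = csfm)
  expect_equal(mean(fodc$csf_fraction[csfm]), 1, tolerance = 0.02)
  Ac <- sh_basis(4, constraint_directions())
  amp_csf <- matrix(fodc$coef, ncol = 15)[which(csfm), ] %*% t(Ac)
  pure <- pure_single_fibre(ph)
  fodp <- csd_fit(dwi, resp, csf_response = cresp, mask = pure)
  amp_wm <- matrix(fodp$coef, ncol = 15)[which(pure), ] %*% t(Ac)
  expect_lt(max(amp_csf), 0.05 * max(amp_wm))
  # constructed 50/50 WM/CSF voxel: fraction recovered within 0.05
  sch <- dwi$scheme
  grid <- grid_geometry(c(16, 16, 16), 3)
  sig <- vapply(seq_along(sch$bvals), function(v) {
    b <- sch$bvals[v]; u <- sch$dirs[v, ]
    adc <- 2e-4 + (1.7e-3 - 2e-4) * u[1]^2
    100 * (0.5 * exp(-b * adc) + 0.5 * exp(-b * 3e-3))
  }, 0)
  mix <- dwi_series(array(rep(sig, each = prod(grid$shape)),
                          dim = c(grid$shape, length(sig))), grid, sch)
  fodm <- csd_fit(mix, resp, csf_response = cresp)
  expect_lt(abs(mean(fodm$csf_fraction) - 0.5), 0.05)
})

test_that("fODF peak extraction handles constructed fields", {
  # single lobe: delta function convolved into SH, peak within 2 degrees
  axis <- c(0.3, -0.5, 0.81); axis <- axis / sqrt(sum(axis^2))
  B1 <- sh_basis(4, matrix(axis, 1))
  coef <- drop(B1) # SH delta at the axis (even part)
  fod <- structure(list(grid = grid_geometry(c(16, 16, 16), 3),
                        coef = array(rep(coef, each = 16^3),
                                     dim = c(16, 16, 16, 15)),
                        lmax = 4, mask = array(TRUE, rep(16, 3)),
                        csf_fraction = NULL), class = "fod_field")
  m1 <- array(FALSE, rep(16, 3)); m1[1] <- TRUE
  pk <- fod_peaks(fod, mask = m1)
  expect_equal(pk$n_peaks, 1L)
  expect_angle_le(pk$peaks[1, , 1], axis, 2)
  # isotropic fODF: no strict local maxima, no peaks
  iso <- fod
  iso$coef[] <- 0; iso$coef[, , , 1] <- 1
  pki <- fod_peaks(iso, mask = m1)
  expect_equal(pki$n_peaks, 0L)
})

test_that("CSD is rotation-equivariant and errors on rank deficiency", {
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  sch <- small_scheme()
  ax0 <- c(1, 0, 0); ax1 <- drop(R %*% ax0)
  d0 <- uniform_tensor_dwi(sch, axis = ax0, n = 8)
  d1 <- uniform_tensor_dwi(rotate_bvecs(R, sch), axis = ax1, n = 8)
  r0 <- estimate_response(d0, min_voxels = 20)
  m <- array(FALSE, rep(8, 3)); m[1] <- TRUE
  p0 <- fod_peaks(csd_fit(d0, r0, mask = m), mask = m)
  p1 <- fod_peaks(csd_fit(d1, r0, mask = m), mask = m)
  expect_angle_le(p1$peaks[1, , 1], ax1, 2)
  expect_angle_le(p0$peaks[1, , 1], ax0, 2)
  # more unknowns than equations
  expect_error(csd_fit(d0, estimate_response(d0, lmax = 8, min_voxels = 20),
                       lmax = 8), "unknowns")
})
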