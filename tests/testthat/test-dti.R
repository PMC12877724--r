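test_that("noiseless WLS recovers the tensor to machine precision", {
  sch <- small_scheme()
  dwi <- uniform_tensor_dwi(sch, evals = c(1.7e-3, 2e-4, 2e-4),
                            axis = c(0, 1, 0))
  tf <- fit_dti_wls(dwi)
  d <- matrix(tf$d, ncol = 6)[1, ]
  expect_equal(d, c(2e-4, 1.7e-3, 2e-4, 0, 0, 0), tolerance = 1e-9)
  expect_equal(matrix(tf$evals, ncol = 3)[1, ],
               c(1.7e-3, 2e-4, 2e-4), tolerance = 1e-9)
  # isotropic voxel has FA below 1e-6
  iso <- uniform_tensor_dwi(sch, evals = rep(1e-3, 3))
  sc <- tensor_scalars(fit_dti_wls(iso))
  expect_lt(max(sc$fa), 1e-6)
  expect_equal(unique(as.vector(round(sc$md, 12))), 1e-3)
})

test_that("rank-deficient direction sets are rejected", {
  es <- electrostatic_directions(5, 1, iterations = 200, restarts = 2,
                                 seed = 1)
  sch5 <- gradient_scheme(c(0, rep(945, 5)), rbind(c(0, 0, 0), es$dirs))
  dwi <- uniform_tensor_dwi(sch5)
  expect_error(fit_dti_wls(dwi), "6 non-collinear")
})

test_that("eigen decomposition reconstructs the tensor", {
  set.seed(8)
  for (i in 1:50) {
    m <- matrix(rnorm(9), 3); A <- (m + t(m)) / 2
    d <- c(A[1, 1], A[2, 2], A[3, 3], A[1, 2], A[1, 3], A[2, 3])
    es <- ulfdwi:::eigen_symmetric3(matrix(d, 1))
    ref <- eigen(A, symmetric = TRUE)
    expect_equal(drop(es$evals), ref$values, tolerance = 1e-10)
    expect_angle_le(drop(es$e1), ref$vectors[, 1], 1e-4)
  }
})

test_that("scalar maps match closed-form FA / MD / DEC", {
  sch <- small_scheme()
  dwi <- uniform_tensor_dwi(sch, evals = c(1.7e-3, 2e-4, 2e-4),
                            axis = c(1, 0, 0))
  sc <- tensor_scalars(fit_dti_wls(dwi))
  expect_equal(unique(as.vector(round(sc$fa, 4))), 0.8704)
  expect_equal(unique(as.vector(round(sc$md, 10))), 0.7e-3)
  dec <- matrix(sc$dec, ncol = 3)
  expect_equal(dec[1, ], c(0.8704, 0, 0), tolerance = 1e-4)
})

test_that("RESTORE matches WLS without outliers and resists corruption", {
  sch <- small_scheme()
  dwi <- uniform_tensor_dwi(sch, evals = c(1.7e-3, 2e-4, 2e-4),
                            axis = c(0, 0, 1), n = 4)
  w <- fit_dti_wls(dwi)
  r <- fit_dti_restore(dwi, sigma = 1)
  expect_equal(matrix(r$d, ncol = 6)[1, ], matrix(w$d, ncol = 6)[1, ],
               tolerance = 5e-3)
  expect_equal(max(r$n_excluded), 0) # no exclusions on clean data
  # corrupt one diffusion volume by a 50% signal drop
  bad <- dwi
  v <- which(sch$bvals > 0)[4]
  bad$data[, , , v] <- bad$data[, , , v] * 0.5
  rb <- fit_dti_restore(bad, sigma = 1)
  wb <- fit_dti_wls(bad)
  lam_r <- matrix(rb$evals, ncol = 3)[1, 1]
  lam_w <- matrix(wb$evals, ncol = 3)[1, 1]
  expect_lt(abs(lam_r - 1.7e-3) / 1.7e-3, 0.05)
  expect_lt(abs(lam_r - 1.7e-3), abs(lam_w - 1.7e-3))
  expect_gte(min(rb$n_excluded), 1)
  # retention rule: when more than n - 7 volumes are flagged as outliers
  # the voxel is marked invalid instead of silently fitted. Perturbing every
  # volume beyond a (deliberately tiny) noise scale triggers it cleanly;
  # majority corruption by consistent scaling is beyond the breakdown point
  # of any robust fitter and cannot be required to be detected.
  jit <- dwi
  set.seed(5)
  jit$data <- jit$data + array(runif(length(jit$data), 0.5, 1),
                               dim = dim(jit$data))
  rw <- fit_dti_restore(jit, sigma = 1e-3)
  # nearly every voxel is invalidated; the rare survivors are voxels whose
  # IRLS fit happens to interpolate exactly 7 rows, and they never carry
  # more exclusions than the n - 7 bound allows
  expect_gt(mean(!rw$valid_fit[rw$mask]), 0.9)
  expect_true(all(rw$n_excluded[rw$mask & rw$valid_fit] <= 12))
  expect_gte(min(rw$n_excluded[rw$mask]), 12)
})

test_that("FA and MD are rotation-equivariant", {
  th <- 35 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  sch <- small_scheme()
  sch_rot <- rotate_bvecs(R, sch)
  d0 <- uniform_tensor_dwi(sch, axis = c(1, 0, 0))
  d1 <- uniform_tensor_dwi(sch_rot, axis = drop(R %*% c(1, 0, 0)))
  s0 <- tensor_scalars(fit_dti_wls(d0))
  s1 <- tensor_scalars(fit_dti_wls(d1))
  expect_equal(s1$fa, s0$fa, tolerance = 1e-8)
  expect_equal(s1$md, s0$md, tolerance = 1e-8)
  t1 <- fit_dti_wls(d1)
  expect_angle_le(matrix(t1$e1, ncol = 3)[1, ], drop(R %*% c(1, 0, 0)), 1e-3)
})

test_that("Rician noise biases FA and MD downward at low SNR", {
  # high-FA voxel population at b = 945: noise-floor suppression, monotone
  sch <- small_scheme()
  snrs <- c(5, 10, 20, 40)
  fa_m <- md_m <- numeric(length(snrs))
  for (i in seq_along(snrs)) {
    dwi <- uniform_tensor_dwi(sch, evals = c(1.7e-3, 2e-4, 2e-4),
                              axis = c(0, 1, 0), n = 12, s0 = 100)
    dwi$data <- add_rician(dwi$data, noise_model(100 / snrs[i], seed = 31 + i))
    sc <- tensor_scalars(fit_dti_wls(dwi, mask = array(TRUE, rep(12, 3))))
    fa_m[i] <- mean(sc$fa)
    md_m[i] <- mean(sc$md)
  }
  # monotone recovery with SNR, up to sampling noise in the population
  # means (the bias saturates to zero above SNR ~ 20)
  expect_true(all(diff(fa_m) > -0.003))
  expect_true(all(diff(md_m) > -0.01e-3))
  expect_gt(fa_m[4] - fa_m[1], 0.01) # clear suppression at SNR 5
  expect_gt(md_m[4] - md_m[1], 0.03e-3)
  expect_lt(fa_m[1], 0.8704)
  expect_lt(md_m[1], 0.7e-3)
  expect_equal(fa_m[4], 0.8704, tolerance = 0.05)
})
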