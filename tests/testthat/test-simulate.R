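test_that("forward attenuation matches the closed form", {
  # single isotropic compartment, D = 0.8e-3 mm^2/s, b = 945 s/mm^2
  sch <- gradient_scheme(c(0, 945), rbind(c(0, 0, 0), c(1, 0, 0)))
  dwi <- uniform_tensor_dwi(sch, evals = rep(0.8e-3, 3))
  expect_equal(dwi$data[1, 1, 1, 2] / dwi$data[1, 1, 1, 1],
               exp(-0.756), tolerance = 1e-12)
  # via the full simulator with a uniform b-scale a = 1.1
  grid <- grid_geometry(c(16, 16, 16), 3)
  ph <- build_phantom(grid, list(
    bundle_cylinder("t", c(0, 0, 0), c(0, 1, 0), 6, 16,
                    evals = rep(0.8e-3, 3))))
  bg <- background_field(grid, "constant",
                         g0 = c(gradient_for_b(945, 35, 42) * 0.1, 0, 0))
  bsc <- b_scale_map(bg, sch, model = "lobe")
  core <- ph$wm > 0.999
  dwi2 <- simulate_dwi(ph, sch, bscale = bsc, s0 = 100)
  # g/G = 0.1 parallel to x: a = 1.21 for the x encoding direction
  expect_equal(unique(round(dwi2$data[, , , 2][core] / 100, 10)),
               round(exp(-1.21 * 0.756), 10))
  # b = 0 volumes carry no diffusion attenuation or a(r) dependence
  expect_equal(unique(dwi2$data[, , , 1][core]), 100)
})

test_that("multi-compartment voxels sum fraction-weighted signals", {
  sch <- gradient_scheme(c(0, 945), rbind(c(0, 0, 0), c(1, 0, 0)))
  ph <- small_phantom()
  dwi <- clean_dwi()
  cx <- balanced_crossing(ph)
  i <- which(cx)[1]
  ijk <- arrayInd(i, ph$grid$shape) - 1
  f1 <- ph$comp_frac[, , , 1][i]; f2 <- ph$comp_frac[, , , 2][i]
  nv <- prod(ph$grid$shape)
  d1 <- matrix(ph$comp_dir[, , , , 1], nv, 3)[i, ]
  d2 <- matrix(ph$comp_dir[, , , , 2], nv, 3)[i, ]
  sch0 <- clean_dwi()$scheme
  v <- which(sch0$bvals > 0)[1]
  u <- sch0$dirs[v, ]
  adc <- function(d) 2e-4 + (1.7e-3 - 2e-4) * sum(u * d)^2
  pred <- 100 * (f1 * exp(-945 * adc(d1)) + f2 * exp(-945 * adc(d2)))
  expect_equal(dwi$data[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1, v], pred,
               tolerance = 1e-10)
})

test_that("echo-train PSF blur behaves like the stated k-space filter", {
  psf <- psf_model(etl = 35, echo_spacing_ms = 8, t2_ms = 80)
  n <- 32
  vol <- array(0, dim = c(n, n, n))
  vol[n / 2, n / 2, n / 2] <- 1
  # T2 -> infinity: unit filter
  psf_inf <- psf_model(etl = 35, echo_spacing_ms = 8, t2_ms = 1e12)
  expect_lt(max(abs(psf_blur(vol, psf_inf) - vol)), 1e-8)
  # point impulse: spread along the phase axes only
  bl <- psf_blur(vol, psf)
  fwhm_axis <- function(img, ax) {
    prof <- switch(ax, img[, n / 2, n / 2], img[n / 2, , n / 2],
                   img[n / 2, n / 2, ])
    sum(prof >= max(prof) / 2)
  }
  expect_equal(fwhm_axis(bl, 1), 1) # readout axis untouched
  expect_gte(fwhm_axis(bl, 2), 1)
  expect_gt(sum(bl > max(bl) / 100), sum(vol > 0)) # energy spread
  # decreasing T2 monotonically broadens the PSF (second-moment width)
  width <- function(t2) {
    b <- psf_blur(vol, psf_model(etl = 35, echo_spacing_ms = 8, t2_ms = t2))
    prof <- b[n / 2, , n / 2] / sum(b[n / 2, , n / 2])
    sum(prof * (seq_len(n) - n / 2)^2)
  }
  w <- vapply(c(160, 80, 40, 20), width, 0)
  expect_true(all(diff(w) > 0))
  # DC (k-space centre) conservation: centre-out ordering weights DC by the
  # first echo, i.e. unattenuated, so the volume mean is conserved
  expect_equal(mean(psf_blur(vol, psf)), mean(vol), tolerance = 1e-9)
  expect_error(psf_model(t2_ms = -1), "positive")
})

test_that("Rician noise sampling matches analytic moments", {
  # sigma = 0 is the identity
  vol <- array(runif(1000, 50, 100), dim = c(10, 10, 10))
  expect_identical(add_rician(vol, noise_model(0)), vol)
  # S = 0: Rayleigh mean sigma sqrt(pi/2)
  z <- array(0, dim = c(100, 100, 100))
  r <- add_rician(z, noise_model(1, seed = 5))
  expect_equal(mean(r), sqrt(pi / 2), tolerance = 0.005 * sqrt(pi / 2))
  expect_gte(min(r), 0)
  # high SNR: Rice first moment ~ sqrt(S^2 + sigma^2)
  s20 <- array(20, dim = c(100, 100, 100))
  r20 <- add_rician(s20, noise_model(1, seed = 6))
  expect_equal(mean(r20), sqrt(20^2 + 1), tolerance = 0.002 * sqrt(401))
  # upward mean bias in the low-SNR regime S < 3 sigma
  s2 <- array(2, dim = c(50, 50, 50))
  r2 <- add_rician(s2, noise_model(1, seed = 7))
  expect_gt(mean(r2), 2)
  # reproducibility
  expect_identical(add_rician(s2, noise_model(1, seed = 7)), r2)
})

test_that("noiseless artifact-free simulation round-trips through DTI", {
  dwi <- clean_dwi()
  ph <- small_phantom()
  tf <- fit_dti_wls(dwi, mask = pure_single_fibre(ph))
  idx <- which(pure_single_fibre(ph))
  d <- matrix(tf$d, ncol = 6)[idx, ]
  truth <- matrix(rep(c(1.7e-3, 2e-4, 2e-4, 0, 0, 0), each = length(idx)),
                  ncol = 6)
  expect_lt(max(abs(d - truth)) / 1.7e-3, 1e-10)
})

test_that("simulation is bit-identical under identical config and seeds", {
  ph <- small_phantom()
  sch <- small_scheme()
  args <- list(ph, sch, bias = bias_field(ph$grid, 0.2, 40, seed = 3),
               psf = psf_model(), noise = noise_model(5, seed = 9), s0 = 100)
  expect_identical(do.call(simulate_dwi, args)$data,
                   do.call(simulate_dwi, args)$data)
})
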