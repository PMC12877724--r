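test_that("bias estimation recovers smooth fields and is near-idempotent", {
  grid <- grid_geometry(c(28, 28, 28), 3)
  co <- ulfdwi:::coordinate_arrays(grid)
  mask <- co$x^2 + co$y^2 + co$z^2 <= 36^2
  # uniform image: estimated field is 1
  flat <- array(100, dim = grid$shape)
  est0 <- estimate_bias(flat, mask, grid)
  expect_lt(max(abs(est0$field[mask] - 1)), 1e-6)
  # piecewise-constant tissue x known smooth field
  tissue <- array(60, dim = grid$shape)
  tissue[co$x^2 + (co$y - 10)^2 + co$z^2 <= 20^2] <- 100
  tissue[!mask] <- 0
  truth <- bias_field(grid, amplitude = 0.3, scale_mm = 40, seed = 11)
  img <- tissue * truth$field
  est <- estimate_bias(img, mask, grid, smoothing_mm = 40)
  expect_gte(stats::cor(est$field[mask], truth$field[mask]), 0.98)
  # approximate idempotence: re-estimating on corrected data gives ~1
  est2 <- estimate_bias(img / est$field, mask, grid, smoothing_mm = 40)
  expect_lt(max(abs(est2$field[mask] - 1)), 0.01)
  expect_error(estimate_bias(img, array(FALSE, grid$shape), grid), "empty")
})

test_that("bias application divides every volume and cancels in S/S0", {
  dwi <- clean_dwi()
  ph <- small_phantom()
  unity <- structure(list(grid = ph$grid, field = array(1, ph$grid$shape)),
                     class = "bias_field")
  expect_equal(apply_bias(dwi, unity)$data, dwi$data)
  bf <- bias_field(ph$grid, 0.25, 40, seed = 2)
  corr <- apply_bias(dwi, bf)
  expect_true(corr$bias_corrected)
  expect_equal(corr$data[, , , 1], dwi$data[, , , 1] / bf$field)
  # a field multiplying all volumes cancels in the fitted tensor
  biased <- dwi
  for (v in seq_len(dim(dwi$data)[4]))
    biased$data[, , , v] <- dwi$data[, , , v] * bf$field
  m <- pure_single_fibre(ph)
  t_ref <- fit_dti_wls(dwi, mask = m)
  t_cor <- fit_dti_wls(apply_bias(biased, bf), mask = m)
  expect_equal(t_cor$d, t_ref$d, tolerance = 1e-9)
  # scalar example: S = 100 divided by field 1.25 gives 80
  one <- unity; one$field[] <- 1.25
  expect_equal(apply_bias(dwi, one)$data[, , , 1],
               dwi$data[, , , 1] / 1.25)
  bad <- unity; bad$field[1] <- 0
  expect_error(apply_bias(dwi, bad), "positive")
})

test_that("background correction inverts the forward model exactly", {
  sch <- gradient_scheme(c(0, 945), rbind(c(0, 0, 0), c(1, 0, 0)))
  # worked example: S0 = 1000, S' = 435.3, a = 1.1 -> S = 469.5, ADC 0.8e-3
  s_corr <- 1000 * (435.3 / 1000)^(1 / 1.1)
  expect_equal(round(s_corr, 1), 469.5)
  expect_equal(-log(s_corr / 1000) / 945, 0.8e-3, tolerance = 1e-3)
  # property: for any a in [0.85, 1.3], forward simulation + correction
  # recovers the true ADC to <= 1e-8 relative error
  grid <- grid_geometry(c(16, 16, 16), 3)
  for (a in c(0.85, 0.95, 1, 1.1, 1.3)) {
    dwi <- uniform_tensor_dwi(sch, evals = rep(0.8e-3, 3), n = 16, a = a)
    amap <- structure(list(grid = grid,
                           a = array(rep(c(1, a), each = prod(grid$shape)),
                                     dim = c(grid$shape, 2))),
                      class = "bscale_map")
    dwi$bias_corrected <- TRUE
    corr <- correct_background(dwi, amap)
    adc <- -log(corr$data[1, 1, 1, 2] / corr$data[1, 1, 1, 1]) / 945
    expect_lt(abs(adc - 0.8e-3) / 0.8e-3, 1e-8)
    if (a == 1) expect_equal(corr$data, dwi$data)
  }
})

test_that("background correction is monotone and commutes with bias removal", {
  sch <- gradient_scheme(c(0, 945), rbind(c(0, 0, 0), c(1, 0, 0)))
  grid <- grid_geometry(c(16, 16, 16), 3)
  dwi <- uniform_tensor_dwi(sch, evals = rep(0.8e-3, 3), n = 16, a = 1.2)
  dwi$bias_corrected <- TRUE
  amap_at <- function(a) structure(
    list(grid = grid, a = array(rep(c(1, a), each = prod(grid$shape)),
                                dim = c(grid$shape, 2))),
    class = "bscale_map")
  # monotone in a: a larger assumed b-scale means the observed attenuation
  # overstates D more, so the corrected signal is restored further above
  # the observed one and the correction magnitude |S - S_obs| grows
  s_seq <- vapply(c(1.05, 1.1, 1.2, 1.3),
                  function(a) correct_background(dwi, amap_at(a))$data[1, 1, 1, 2],
                  0)
  expect_true(all(diff(s_seq) > 0))
  expect_true(all(s_seq > dwi$data[1, 1, 1, 2]))
  # commutation with the (voxel-wise multiplicative) bias correction
  bf <- bias_field(grid, 0.2, 40, seed = 3)
  biased <- dwi
  for (v in 1:2) biased$data[, , , v] <- dwi$data[, , , v] * bf$field
  path1 <- correct_background(apply_bias(biased, bf), amap_at(1.2))
  path2 <- apply_bias({
    b2 <- biased; b2$bias_corrected <- TRUE
    correct_background(b2, amap_at(1.2))
  }, bf)
  expect_equal(path1$data, path2$data, tolerance = 1e-12)
})

test_that("noise sigma estimation is Rayleigh-consistent and equivariant", {
  ph <- small_phantom()
  sch <- small_scheme()
  dwi <- simulate_dwi(ph, sch, noise = noise_model(5, seed = 21), s0 = 100)
  # pure Rician background with a known mask: within 5%
  est_pure <- estimate_noise_sigma(dwi, background_mask = !ph$head)
  expect_equal(est_pure, 5, tolerance = 0.05)
  # automatic background detection stays close
  est <- estimate_noise_sigma(dwi)
  expect_equal(est, 5, tolerance = 0.15)
  # scaling the data scales the estimate
  dwi2 <- dwi; dwi2$data <- dwi2$data * 3
  expect_equal(estimate_noise_sigma(dwi2), 3 * est, tolerance = 1e-12)
  # zero-noise data: estimate ~ 0
  expect_lt(estimate_noise_sigma(clean_dwi()), 1e-9)
  # manual override is returned untouched
  expect_equal(estimate_noise_sigma(dwi, override = 7.5), 7.5)
  tiny <- array(FALSE, ph$grid$shape); tiny[1:3, 1, 1] <- TRUE
  expect_error(estimate_noise_sigma(dwi, background_mask = tiny),
               "too small")
})
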