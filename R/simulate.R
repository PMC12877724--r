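#' DWI series container
#'
#' @param data 4D array (x, y, z, volume) of non-negative magnitudes.
#' @param grid a [grid_geometry()].
#' @param scheme a [gradient_scheme()] with as many volumes as `data`.
#' @param bias_corrected,background_corrected provenance flags.
#' @return object of class `dwi_series`.
#' @export
dwi_series <- function(data, grid, scheme,
                       bias_corrected = FALSE, background_corrected = FALSE) {
  stopifnot(length(dim(data)) == 4, all(dim(data)[1:3] == grid$shape),
            dim(data)[4] == n_volumes(scheme))
  if (sum(scheme$bvals == 0) < 1)
    stop("series must contain at least one b = 0 volume", call. = FALSE)
  structure(list(data = data, grid = grid, scheme = scheme,
                 bias_corrected = bias_corrected,
                 background_corrected = background_corrected),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("dwi series %s x %d volumes%s%s\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
              if (x$bias_corrected) ", bias-corrected" else "",
              if (x$background_corrected) ", background-corrected" else ""))
  invisible(x)
}

#' Echo-train point-spread-function model
#'
#' Fast-spin-echo readouts acquire successive phase-encode lines at later
#' echoes; T2 decay across the train attenuates the k-space periphery and
#' broadens the image-domain PSF along the phase axes. The model is a k-space
#' amplitude filter exp(-t(k)/T2) with t(k) the acquisition time of line k
#' under the stated ordering; the first echo is at t = 0, so centre-out
#' ordering leaves the DC line unattenuated.
#'
#' @param etl echo train length (echoes per excitation).
#' @param echo_spacing_ms time between successive echoes, ms.
#' @param t2_ms tissue T2, ms.
#' @param ordering `"centre_out"` (default) or `"linear"` phase ordering.
#' @param phase_axes the two phase-encoded axes (readout is fully sampled).
#' @return object of class `psf_model`.
#' @export
psf_model <- function(etl = 35, echo_spacing_ms = 8, t2_ms = 80,
                      ordering = c("centre_out", "linear"),
                      phase_axes = c(2, 3)) {
  ordering <- match.arg(ordering)
  if (etl <= 0 || echo_spacing_ms <= 0 || t2_ms <= 0)
    stop("PSF model parameters must be positive", call. = FALSE)
  stopifnot(length(phase_axes) == 2, all(phase_axes %in% 1:3))
  structure(list(etl = etl, echo_spacing_ms = echo_spacing_ms, t2_ms = t2_ms,
                 ordering = ordering, phase_axes = phase_axes),
            class = "psf_model")
}

# per-frequency-bin k-space weights for an axis of length n
psf_weights <- function(n, psf) {
  f <- 0:(n - 1)
  f[f > n / 2] <- f[f > n / 2] - n # signed frequency per FFT bin
  # +k and -k are acquired adjacently under centre-out ordering; the
  # averaged rank keeps the filter symmetric (hence real-valued)
  ord_idx <- switch(psf$ordering,
    centre_out = rank(abs(f), ties.method = "average") - 1,
    linear = rank(f, ties.method = "first") - 1)
  echo <- if (n > 1) ord_idx / (n - 1) * (psf$etl - 1) else 0
  exp(-psf$echo_spacing_ms * echo / psf$t2_ms)
}

#' Apply echo-train PSF blur to a volume
#'
#' Multiplies k-space by the echo-decay filter separately along each phase
#' axis and returns the magnitude of the inverse transform.
#'
#' @param volume 3D array.
#' @param psf a [psf_model()].
#' @return blurred non-negative 3D array of the same shape.
#' @export
psf_blur <- function(volume, psf) {
  stopifnot(length(dim(volume)) == 3)
  v <- volume + 0i
  for (ax in psf$phase_axes) {
    w <- psf_weights(dim(volume)[ax], psf)
    v <- fft_axis(v, ax, inverse = FALSE)
    v <- sweep_axis(v, ax, w)
    v <- fft_axis(v, ax, inverse = TRUE) / dim(volume)[ax]
  }
  Mod(v)
}

fft_axis <- function(vol, axis, inverse) {
  d <- dim(vol)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  dm <- dim(v)
  m <- matrix(v, nrow = dm[1])
  m <- stats::mvfft(m, inverse = inverse)
  aperm(array(m, dim = dm), order(perm))
}

sweep_axis <- function(vol, axis, w) {
  d <- dim(vol)
  wa <- switch(axis,
    `1` = array(w, dim = d),
    `2` = array(rep(w, each = d[1]), dim = d),
    `3` = array(rep(w, each = d[1] * d[2]), dim = d))
  vol * wa
}

#' Rician noise model and sampler
#'
#' Magnitude images carry Rician noise: the observed value is
#' sqrt((S + n1)^2 + n2^2) with n1, n2 independent zero-mean Gaussians of
#' scale sigma.
#'
#' @param sigma noise scale in signal units (>= 0).
#' @param seed RNG seed.
#' @return `noise_model` object.
#' @export
noise_model <- function(sigma, seed = 1) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, seed = seed), class = "noise_model")
}

#' @rdname noise_model
#' @param volume array of noise-free magnitudes.
#' @param noise a `noise_model`.
#' @export
add_rician <- function(volume, noise) {
  if (noise$sigma == 0) return(volume)
  n <- length(volume)
  with_seed(noise$seed, {
    n1 <- stats::rnorm(n, sd = noise$sigma)
    n2 <- stats::rnorm(n, sd = noise$sigma)
    array(sqrt((as.vector(volume) + n1)^2 + n2^2), dim = dim(volume))
  })
}

#' Simulate an ultra-low-field DWI acquisition on a phantom
#'
#' Forward model per voxel r and encoding direction u:
#' S(r, u) = s0 b1(r) [ sum_c f_c exp(-a(r, u) b u' D_c u)
#'                      + f_csf exp(-a b D_csf) + f_gm exp(-a b D_gm) ],
#' i.e. a fraction-weighted sum of single-tensor compartments with the
#' spatially varying b-scale a(r, u) from the background field gradient and
#' a multiplicative B1 bias. The echo-train PSF is applied per volume after
#' attenuation; Rician noise is applied last. b = 0 volumes carry no
#' diffusion attenuation and no a(r) dependence.
#'
#' @param truth a [build_phantom()] result.
#' @param scheme a [gradient_scheme()].
#' @param bg optional [background_field()]; NULL means a(r) = 1.
#' @param bias optional [bias_field()]; NULL means unity.
#' @param psf optional [psf_model()]; NULL means no blur.
#' @param noise optional [noise_model()]; NULL means noise-free.
#' @param s0 proton-density signal level in WM, arbitrary units.
#' @param bscale_model b-scaling strategy passed to [b_scale_map()].
#' @param bscale optional precomputed [b_scale_map()] (overrides `bg`).
#' @return a [dwi_series()].
#' @export
simulate_dwi <- function(truth, scheme, bg = NULL, bias = NULL, psf = NULL,
                         noise = NULL, s0 = 100,
                         bscale_model = c("lobe", "cross_term"),
                         bscale = NULL) {
  bscale_model <- match.arg(bscale_model)
  grid <- truth$grid
  if (!is.null(bg)) stop_if_grid_mismatch(grid, bg$grid, "phantom and background field")
  if (!is.null(bias)) stop_if_grid_mismatch(grid, bias$grid, "phantom and bias field")
  if (is.null(bscale) && !is.null(bg))
    bscale <- b_scale_map(bg, scheme, model = bscale_model)
  if (!is.null(bscale))
    stop_if_grid_mismatch(grid, bscale$grid, "phantom and b-scale map")
  s <- grid$shape
  nv <- n_volumes(scheme)
  nvox <- prod(s)
  K <- dim(truth$comp_frac)[4]
  f_comp <- matrix(truth$comp_frac, nvox, K)
  dirs <- array(truth$comp_dir, dim = c(nvox, 3, K))
  evals <- array(truth$comp_evals, dim = c(nvox, 3, K))
  csf <- as.vector(truth$csf); gm <- as.vector(truth$gm)
  tissue_tot <- rowSums(f_comp) + csf + gm
  biasv <- if (is.null(bias)) 1 else as.vector(bias$field)
  data <- array(0, dim = c(s, nv))
  for (v in seq_len(nv)) {
    b <- scheme$bvals[v]
    if (b == 0) {
      sig <- s0 * tissue_tot
    } else {
      u <- scheme$dirs[v, ]
      a <- if (is.null(bscale)) 1 else as.vector(bscale$a[, , , v])
      sig <- csf * exp(-a * b * truth$csf_adc) + gm * exp(-a * b * truth$gm_adc)
      for (k in seq_len(K)) {
        fk <- f_comp[, k]
        act <- fk > 0
        if (!any(act)) next
        du <- dirs[act, 1, k] * u[1] + dirs[act, 2, k] * u[2] +
              dirs[act, 3, k] * u[3]
        lam_perp <- (evals[act, 2, k] + evals[act, 3, k]) / 2
        adc <- lam_perp + (evals[act, 1, k] - lam_perp) * du^2
        av <- if (length(a) == 1) a else a[act]
        sig[act] <- sig[act] + fk[act] * exp(-av * b * adc)
      }
      sig <- s0 * sig
    }
    vol <- array(sig * biasv, dim = s)
    if (!is.null(psf)) vol <- psf_blur(vol, psf)
    data[, , , v] <- vol
  }
  if (!is.null(noise) && noise$sigma > 0) {
    data <- add_rician(data, noise)
  }
  dwi_series(data, grid, scheme)
}
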