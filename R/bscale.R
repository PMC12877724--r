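#' Background B0 gradient field models
#'
#' On permanent-magnet ultra-low-field systems the static field carries a
#' large built-in gradient (up to ~1.4 mT/m at 8 cm from isocentre on the
#' system modelled here), which adds to the diffusion-encoding gradients and
#' perturbs the realised b-value. This constructor builds simple analytic
#' models of that field on a grid.
#'
#' @param grid a [grid_geometry()].
#' @param model `"linear"`: magnitude grows linearly with distance from the
#'   isocentre along `axis`, reaching `edge_mT_m` at `edge_mm`; `"constant"`:
#'   uniform vector field `g0`.
#' @param edge_mT_m magnitude at `edge_mm` (linear model), mT/m.
#' @param edge_mm calibration distance from isocentre, mm.
#' @param axis axis index (1 = x/RL, 2 = y, 3 = z) along which the linear
#'   model varies and points.
#' @param asymmetry factor applied to the negative half-space along `axis`
#'   (the magnet is asymmetric in the RL direction; 1 = symmetric).
#' @param g0 length-3 vector, mT/m (constant model only).
#' @return object of class `background_field`: grid plus a `shape x 3` array
#'   `g` in mT/m.
#' @export
background_field <- function(grid, model = c("linear", "constant"),
                             edge_mT_m = 1.4, edge_mm = 80, axis = 1,
                             asymmetry = 1, g0 = NULL) {
  model <- match.arg(model)
  if (edge_mT_m < 0) stop("edge magnitude must be >= 0", call. = FALSE)
  if (edge_mm <= 0) stop("edge distance must be > 0", call. = FALSE)
  s <- grid$shape
  g <- array(0, dim = c(s, 3))
  if (model == "constant") {
    if (is.null(g0)) g0 <- c(edge_mT_m, 0, 0)
    for (ax in 1:3) g[, , , ax] <- g0[ax]
  } else {
    co <- coordinate_arrays(grid)[[axis]]
    val <- co / edge_mm * edge_mT_m
    val[co < 0] <- val[co < 0] * asymmetry
    g[, , , axis] <- val
  }
  structure(list(grid = grid, g = g), class = "background_field")
}

bg_magnitude <- function(bg) {
  sqrt(bg$g[, , , 1]^2 + bg$g[, , , 2]^2 + bg$g[, , , 3]^2)
}

#' Dephasing-moment integrals for PGSE with a constant background gradient
#'
#' For a spin echo at `te` with monopolar encoding lobes placed symmetrically
#' about the refocusing pulse, the b-value in the presence of a constant
#' background gradient g is
#'   b(G, g) = gamma^2 (G^2 I_GG + 2 (G.g) I_Gg + |g|^2 I_gg),
#' where the I are time integrals of products of the zeroth gradient moments
#' (the applied-lobe moment and the background moment with its sign flip at
#' te/2). Returns the ratios I_Gg/I_GG and I_gg/I_GG that scale the cross and
#' background terms relative to the nominal b.
#'
#' @param delta,Delta lobe duration and separation, ms.
#' @param te echo time, ms; lobes are centred about te/2.
#' @return list with `kappa_cross` (= I_Gg/I_GG) and `kappa_bg` (= I_gg/I_GG).
#' @export
pgse_cross_ratios <- function(delta, Delta, te) {
  check_pgse_timing(delta, Delta)
  if (te < Delta + delta)
    stop("echo time too short for the lobes (te >= Delta + delta required)",
         call. = FALSE)
  tau <- te / 2
  t1 <- tau - (Delta + delta) / 2 # symmetric placement about the 180 pulse
  t2 <- t1 + Delta
  FG <- function(t) {
    ifelse(t < t1, 0,
    ifelse(t < t1 + delta, t - t1,
    ifelse(t < t2, delta,
    ifelse(t < t2 + delta, delta - (t - t2), 0))))
  }
  Fg <- function(t) pmin(t, te - t)
  brk <- sort(unique(c(0, t1, t1 + delta, tau, t2, t2 + delta, te)))
  simpson <- function(f, a, b) (b - a) / 6 * (f(a) + 4 * f((a + b) / 2) + f(b))
  i_gg <- i_xg <- 0
  for (s in seq_len(length(brk) - 1)) {
    a <- brk[s]; b <- brk[s + 1]
    i_xg <- i_xg + simpson(function(t) FG(t) * Fg(t), a, b)
    i_gg <- i_gg + simpson(function(t) Fg(t)^2, a, b)
  }
  i_GG <- delta^2 * (Delta - delta / 3)
  list(kappa_cross = i_xg / i_GG, kappa_bg = i_gg / i_GG)
}

#' Per-direction b-value scaling factor from a background gradient
#'
#' The scale a such that the realised b-value is a times the prescribed one.
#' Two strategies are provided:
#' \describe{
#'   \item{`"lobe"`}{the background gradient is added to the encoding lobes
#'     only: a = ||G u + g||^2 / G^2 = 1 + 2 (g.u)/G + |g|^2/G^2.}
#'   \item{`"cross_term"`}{the background gradient acts over the whole echo
#'     time; the linear-in-g cross term accumulated between excitation and
#'     echo gives a = 1 + 2 kappa (g.u)/G with kappa from
#'     [pgse_cross_ratios()]. With `include_quadratic = TRUE` the
#'     background-only term kappa_bg |g|^2/G^2 is added as well (it is below
#'     1% at the field strengths modelled here and the model is otherwise a
#'     pure linear scaling in g).}
#' }
#'
#' @param g length-3 background gradient vector, or n x 3 matrix, mT/m.
#' @param u length-3 unit encoding direction.
#' @param G encoding gradient amplitude, mT/m.
#' @param model `"lobe"` or `"cross_term"`.
#' @param delta,Delta,te PGSE timings, ms (cross-term model only).
#' @param include_quadratic add the background-only quadratic term.
#' @return scale factor(s) a, dimensionless.
#' @export
b_scale_factor <- function(g, u, G, model = c("lobe", "cross_term"),
                           delta = 35, Delta = 42, te = 84,
                           include_quadratic = FALSE) {
  model <- match.arg(model)
  if (G <= 0) stop("encoding gradient amplitude must be positive", call. = FALSE)
  g <- rbind3(g)
  gu <- drop(g %*% u)
  g2 <- rowSums(g^2)
  if (model == "lobe") {
    1 + 2 * gu / G + g2 / G^2
  } else {
    k <- pgse_cross_ratios(delta, Delta, te)
    a <- 1 + 2 * k$kappa_cross * gu / G
    if (include_quadratic) a <- a + k$kappa_bg * g2 / G^2
    a
  }
}

#' Map of per-voxel, per-volume b-scaling factors
#'
#' @param bg a [background_field()].
#' @param scheme a [gradient_scheme()]; must have positive gradient amplitude
#'   on the diffusion-weighted volumes.
#' @param model,include_quadratic see [b_scale_factor()].
#' @param collapse `"none"` keeps the per-direction factors; `"worst"`
#'   replaces them with the direction-collapsed worst case (g parallel to u),
#'   a scalar map per voxel replicated over volumes.
#' @return object of class `bscale_map`: grid plus array `a` of dim
#'   `c(shape, n volumes)`; identically 1 on b = 0 volumes.
#' @export
b_scale_map <- function(bg, scheme, model = c("lobe", "cross_term"),
                        include_quadratic = FALSE,
                        collapse = c("none", "worst")) {
  model <- match.arg(model)
  collapse <- match.arg(collapse)
  s <- bg$grid$shape
  nv <- n_volumes(scheme)
  dw <- dw_index(scheme)
  if (length(dw) > 0 && scheme$G <= 0)
    stop("scheme has no positive gradient amplitude", call. = FALSE)
  a <- array(1, dim = c(s, nv))
  G <- scheme$G
  gx <- bg$g[, , , 1]; gy <- bg$g[, , , 2]; gz <- bg$g[, , , 3]
  g2 <- gx^2 + gy^2 + gz^2
  k <- if (model == "cross_term")
    pgse_cross_ratios(scheme$delta, scheme$Delta, scheme$te) else NULL
  if (collapse == "worst") {
    gmag <- sqrt(g2)
    aw <- if (model == "lobe") (1 + gmag / G)^2
          else 1 + 2 * k$kappa_cross * gmag / G +
               if (include_quadratic) k$kappa_bg * g2 / G^2 else 0
    for (v in dw) a[, , , v] <- aw
    return(structure(list(grid = bg$grid, a = a), class = "bscale_map"))
  }
  for (v in dw) {
    u <- scheme$dirs[v, ]
    gu <- gx * u[1] + gy * u[2] + gz * u[3]
    a[, , , v] <- if (model == "lobe") {
      1 + 2 * gu / G + g2 / G^2
    } else {
      1 + 2 * k$kappa_cross * gu / G +
        (if (include_quadratic) k$kappa_bg * g2 / G^2 else 0)
    }
  }
  structure(list(grid = bg$grid, a = a), class = "bscale_map")
}

#' ADC error incurred by ignoring the b-scaling
#'
#' When the realised b-value is a times the prescribed one and the log-linear
#' fit assumes the prescribed value, the fitted ADC is a times the true ADC;
#' the relative error is (a - 1) x 100 percent.
#'
#' @param a b-scaling factor(s).
#' @return relative ADC error in percent.
#' @export
uncorrected_adc_error <- function(a) {
  if (any(a <= 0)) stop("a must be positive", call. = FALSE)
  (a - 1) * 100
}
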