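#' Real even spherical-harmonic basis
#'
#' Antipodally symmetric (even-order) real spherical harmonics, orthonormal
#' on the unit sphere. Coefficient ordering: l ascending over even orders,
#' and within each order m from -l to +l. The convention is
#' \itemize{
#'   \item m = 0: N(l,0) P_l^0(cos theta)
#'   \item m > 0: sqrt(2) N(l,m) P_l^m(cos theta) cos(m phi)
#'   \item m < 0: sqrt(2) N(l,|m|) P_l^|m|(cos theta) sin(|m| phi)
#' }
#' with N(l,m) = sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!) and associated Legendre
#' functions including the Condon-Shortley phase. Note that toolkits differ
#' in their real-SH dialects (some order m descending, some swap the
#' sin/cos halves); coefficients from other software must be converted.
#'
#' @param lmax maximum (even) harmonic order.
#' @param dirs n x 3 matrix of unit direction vectors.
#' @return n x ((lmax+1)(lmax+2)/2) design matrix.
#' @export
sh_basis <- function(lmax, dirs) {
  if (lmax %% 2 != 0) stop("lmax must be even", call. = FALSE)
  dirs <- unit_rows(rbind3(dirs))
  ct <- pmin(pmax(dirs[, 3], -1), 1)
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  ncoef <- (lmax + 1) * (lmax + 2) / 2
  B <- matrix(0, n, ncoef)
  col <- 1
  for (l in seq(0, lmax, by = 2)) {
    P <- assoc_legendre(l, ct) # (l+1) columns, m = 0..l
    for (m in -l:l) {
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      B[, col] <-
        if (m == 0) N * P[, 1]
        else if (m > 0) sqrt(2) * N * P[, m + 1] * cos(m * phi)
        else sqrt(2) * N * P[, am + 1] * sin(am * phi)
      col <- col + 1
    }
  }
  B
}

#' Number of even-SH coefficients up to order lmax
#' @param lmax even harmonic order.
#' @export
sh_ncoef <- function(lmax) (lmax + 1) * (lmax + 2) / 2

# associated Legendre P_l^m(x) for m = 0..l (Condon-Shortley phase),
# vectorised over x; standard stable recurrences
assoc_legendre <- function(l, x) {
  out <- matrix(0, length(x), l + 1)
  somx2 <- sqrt(pmax(0, 1 - x^2))
  for (m in 0:l) {
    # P_m^m
    pmm <- rep(1, length(x))
    if (m > 0) pmm <- (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * somx2^m
    if (l == m) { out[, m + 1] <- pmm; next }
    pmmp1 <- x * (2 * m + 1) * pmm # P_{m+1}^m
    if (l == m + 1) { out[, m + 1] <- pmmp1; next }
    for (ll in (m + 2):l) {
      pll <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
      pmm <- pmmp1; pmmp1 <- pll
    }
    out[, m + 1] <- pmmp1
  }
  out
}

# indices of the zonal (m = 0) coefficients within the even-SH ordering
zonal_index <- function(lmax) {
  idx <- integer(0); col <- 1
  for (l in seq(0, lmax, by = 2)) {
    idx <- c(idx, col + l) # m runs -l..l, m=0 sits l positions in
    col <- col + 2 * l + 1
  }
  idx
}

# orders l per coefficient column
sh_orders <- function(lmax) {
  unlist(lapply(seq(0, lmax, by = 2), function(l) rep(l, 2 * l + 1)))
}

#' Quasi-uniform direction sets on the sphere
#'
#' `fibonacci_axes()` returns a deterministic spiral-lattice point set made
#' antipodally symmetric (n/2 axes and their negatives, n even);
#' `constraint_directions()` returns the 300-point electrostatically
#' optimised set shipped with the package, used as the amplitude-constraint
#' grid in constrained spherical deconvolution.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_axes <- function(n = 724) {
  stopifnot(n %% 2 == 0)
  m <- n / 2
  i <- seq_len(m) - 0.5
  ga <- pi * (3 - sqrt(5))
  z <- 1 - i / m # upper hemisphere
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- ga * i
  p <- cbind(r * cos(phi), r * sin(phi), z)
  rbind(p, -p)
}

#' @rdname fibonacci_axes
#' @export
constraint_directions <- function() {
  path <- system.file("extdata", "constraint300.txt", package = "ulfdwi")
  if (path == "") path <- file.path("inst", "extdata", "constraint300.txt")
  as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
}
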