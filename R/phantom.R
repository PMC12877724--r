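#' Digital fibre phantoms for ultra-low-field diffusion simulation
#'
#' A phantom is a voxelised "ground truth": per-voxel fibre compartments
#' (orientation, volume fraction, tensor eigenvalues), WM/GM/CSF tissue
#' fraction maps, named bundle masks and bundle centrelines. It stands in
#' for the tissue segmentations and anatomy that in-vivo work takes from a
#' structural scan, so that recovery can be scored exactly.
#'
#' @name phantom
NULL

WM_EVALS_DEFAULT <- c(1.7e-3, 0.2e-3, 0.2e-3) # mm^2/s
CSF_ADC <- 3.0e-3  # mm^2/s, isotropic
GM_ADC <- 0.8e-3   # mm^2/s, isotropic

#' Phantom structure constructors
#'
#' `bundle_cylinder()` is a straight tube, `bundle_arc()` a circular-arc tube
#' (torus segment), `csf_ellipsoid()` an isotropic free-water compartment.
#' All coordinates are world mm; orientations are the local tube tangent.
#'
#' @param name bundle name (used for masks and centrelines).
#' @param center length-3 world centre, mm.
#' @param axis cylinder axis (unit vector, normalised internally).
#' @param radius tube radius, mm (cylinder/arc) .
#' @param half_length half length along the axis, mm.
#' @param evals length-3 tensor eigenvalues, mm^2/s, axial first.
#' @param fraction fibre volume fraction contributed by the structure.
#' @param e1,e2 orthonormal in-plane axes of the arc plane.
#' @param arc_radius centreline radius of the arc, mm.
#' @param theta_deg length-2 angular range of the arc, degrees, measured from
#'   `e1` towards `e2`.
#' @param semiaxes length-3 ellipsoid semi-axes, mm.
#' @return a structure description (list) consumed by [build_phantom()].
#' @export
bundle_cylinder <- function(name, center, axis, radius, half_length,
                            evals = WM_EVALS_DEFAULT, fraction = 1) {
  axis <- axis / sqrt(sum(axis^2))
  list(kind = "cylinder", name = name, center = center, axis = axis,
       radius = radius, half_length = half_length, evals = evals,
       fraction = fraction)
}

#' @rdname bundle_cylinder
#' @export
bundle_arc <- function(name, center, e1, e2, arc_radius, radius,
                       theta_deg = c(0, 180), evals = WM_EVALS_DEFAULT,
                       fraction = 1) {
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- e2 - sum(e2 * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  list(kind = "arc", name = name, center = center, e1 = e1, e2 = e2,
       arc_radius = arc_radius, radius = radius, theta = theta_deg * pi / 180,
       evals = evals, fraction = fraction)
}

#' @rdname bundle_cylinder
#' @export
csf_ellipsoid <- function(center, semiaxes, fraction = 1) {
  list(kind = "csf_ellipsoid", name = "csf", center = center,
       semiaxes = semiaxes, fraction = fraction)
}

structure_extent <- function(st) {
  # conservative world-space bounding box corners
  switch(st$kind,
    cylinder = {
      r <- abs(st$axis) * st$half_length +
        st$radius * sqrt(pmax(0, 1 - st$axis^2))
      rbind(st$center - r, st$center + r)
    },
    arc = {
      e3 <- cross3(st$e1, st$e2)
      r <- (st$arc_radius + st$radius) * sqrt(st$e1^2 + st$e2^2) +
        st$radius * abs(e3)
      rbind(st$center - r, st$center + r)
    },
    csf_ellipsoid = rbind(st$center - st$semiaxes, st$center + st$semiaxes))
}

# logical membership of world points (x, y, z arrays) in a structure
structure_inside <- function(st, x, y, z) {
  px <- x - st$center[1]; py <- y - st$center[2]; pz <- z - st$center[3]
  switch(st$kind,
    cylinder = {
      t <- px * st$axis[1] + py * st$axis[2] + pz * st$axis[3]
      r2 <- (px - t * st$axis[1])^2 + (py - t * st$axis[2])^2 +
            (pz - t * st$axis[3])^2
      abs(t) <= st$half_length & r2 <= st$radius^2
    },
    arc = {
      q1 <- px * st$e1[1] + py * st$e1[2] + pz * st$e1[3]
      q2 <- px * st$e2[1] + py * st$e2[2] + pz * st$e2[3]
      e3 <- cross3(st$e1, st$e2)
      qn <- px * e3[1] + py * e3[2] + pz * e3[3]
      rho <- sqrt(q1^2 + q2^2)
      ring <- sqrt((rho - st$arc_radius)^2 + qn^2) <= st$radius
      th <- atan2(q2, q1)
      th[th < st$theta[1] - 1e-9] <- th[th < st$theta[1] - 1e-9] + 2 * pi
      ring & th >= st$theta[1] - 1e-9 & th <= st$theta[2] + 1e-9
    },
    csf_ellipsoid = {
      (px / st$semiaxes[1])^2 + (py / st$semiaxes[2])^2 +
        (pz / st$semiaxes[3])^2 <= 1
    })
}

# unit tangent field of a bundle structure at world points (list of 3 arrays)
structure_tangent <- function(st, x, y, z) {
  if (st$kind == "cylinder") {
    list(tx = array(st$axis[1], dim = dim(x)),
         ty = array(st$axis[2], dim = dim(x)),
         tz = array(st$axis[3], dim = dim(x)))
  } else {
    px <- x - st$center[1]; py <- y - st$center[2]; pz <- z - st$center[3]
    q1 <- px * st$e1[1] + py * st$e1[2] + pz * st$e1[3]
    q2 <- px * st$e2[1] + py * st$e2[2] + pz * st$e2[3]
    th <- atan2(q2, q1)
    tx <- -sin(th) * st$e1[1] + cos(th) * st$e2[1]
    ty <- -sin(th) * st$e1[2] + cos(th) * st$e2[2]
    tz <- -sin(th) * st$e1[3] + cos(th) * st$e2[3]
    list(tx = tx, ty = ty, tz = tz)
  }
}

structure_centreline <- function(st, spacing_mm = 1) {
  if (st$kind == "cylinder") {
    t <- seq(-st$half_length, st$half_length, by = spacing_mm)
    outer(t, st$axis) + rep(st$center, each = length(t))
  } else {
    arclen <- (st$theta[2] - st$theta[1]) * st$arc_radius
    th <- seq(st$theta[1], st$theta[2], length.out = max(2, ceiling(arclen / spacing_mm)))
    p <- st$arc_radius * (outer(cos(th), st$e1) + outer(sin(th), st$e2))
    p + rep(st$center, each = length(th))
  }
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build a phantom from structure descriptions
#'
#' Tissue fractions are computed by supersampling each voxel
#' (`supersample`^3 subpoints against the analytic geometry), which creates
#' realistic partial-volume boundaries and a non-empty GM/WM interface. The
#' head is a sphere whose outer shell of thickness `rind_mm` is grey matter;
#' interior tissue that belongs to no fibre bundle or CSF structure is also
#' labelled grey matter (deep GM), so bundles are embedded in GM and
#' anatomically constrained tracking terminates at their ends.
#'
#' @param grid a [grid_geometry()]; at least 16 voxels per axis.
#' @param structures list of structure descriptions
#'   ([bundle_cylinder()], [bundle_arc()], [csf_ellipsoid()]).
#' @param head_radius_mm head sphere radius, mm.
#' @param supersample per-axis subsampling factor for partial volumes.
#' @param max_compartments maximum fibre compartments per voxel.
#' @return object of class `phantom_truth`.
#' @export
build_phantom <- function(grid, structures, head_radius_mm = NULL,
                          supersample = 2, max_compartments = 2) {
  s <- grid$shape
  if (any(s < 16)) stop("phantom grid must be at least 16 voxels per axis",
                        call. = FALSE)
  if (is.null(head_radius_mm))
    head_radius_mm <- min((s - 2) / 2 * grid$vox_mm) - grid$vox_mm
  lo <- vox2world(grid, c(0, 0, 0)) - grid$vox_mm / 2
  hi <- vox2world(grid, s - 1) + grid$vox_mm / 2
  for (st in structures) {
    ext <- structure_extent(st)
    if (any(ext[1, ] < lo) || any(ext[2, ] > hi))
      stop(sprintf("structure '%s' extends outside the grid", st$name),
           call. = FALSE)
  }
  co <- coordinate_arrays(grid)
  offs <- (seq_len(supersample) - (supersample + 1) / 2) / supersample *
    grid$vox_mm
  bundles <- Filter(function(st) st$kind != "csf_ellipsoid", structures)
  csfs <- Filter(function(st) st$kind == "csf_ellipsoid", structures)
  frac_of <- function(st) {
    f <- array(0, dim = s)
    for (ox in offs) for (oy in offs) for (oz in offs)
      f <- f + structure_inside(st, co$x + ox, co$y + oy, co$z + oz)
    f / supersample^3
  }
  head_frac <- array(0, dim = s)
  for (ox in offs) for (oy in offs) for (oz in offs)
    head_frac <- head_frac +
      ((co$x + ox)^2 + (co$y + oy)^2 + (co$z + oz)^2 <= head_radius_mm^2)
  head_frac <- head_frac / supersample^3

  bundle_frac <- lapply(bundles, frac_of)
  names(bundle_frac) <- vapply(bundles, `[[`, "", "name")
  csf <- array(0, dim = s)
  for (st in csfs) csf <- csf + st$fraction * frac_of(st)

  fib_total <- array(0, dim = s)
  for (i in seq_along(bundles))
    fib_total <- fib_total + bundles[[i]]$fraction * bundle_frac[[i]]
  wm <- pmin(fib_total, 1)
  if (any(csf + wm > 1 + 1e-9)) {
    over <- csf + wm > 1 + 1e-9
    # CSF and fibre structures overlapping is a composition error
    if (max(csf[over]) > 1e-9 && max(wm[over]) > 1e-9)
      stop("overlapping structure fractions exceed 1 (CSF and fibre bundles intersect)",
           call. = FALSE)
  }
  csf <- pmin(csf, 1 - wm)
  gm <- pmax(0, head_frac - wm - csf)

  # assign up to max_compartments fibre compartments per voxel, largest first
  K <- max_compartments
  comp_frac <- array(0, dim = c(s, K))
  comp_dir <- array(0, dim = c(s, 3, K))
  comp_evals <- array(0, dim = c(s, 3, K))
  if (length(bundles) > 0) {
    contrib <- array(0, dim = c(s, length(bundles)))
    for (i in seq_along(bundles))
      contrib[, , , i] <- bundles[[i]]$fraction * bundle_frac[[i]]
    norm <- pmax(fib_total, 1e-12)
    tangents <- lapply(bundles, structure_tangent, co$x, co$y, co$z)
    # rank bundles per voxel by contribution; keep the K largest
    flat <- matrix(contrib, ncol = length(bundles))
    ord <- if (length(bundles) == 1) matrix(1L, nrow(flat), 1)
           else t(apply(flat, 1, order, decreasing = TRUE))
    nv <- prod(s)
    share <- matrix(wm, nv) # total fibre fraction to distribute
    flat_norm <- flat / matrix(norm, nv, length(bundles))
    for (slot in seq_len(min(K, length(bundles)))) {
      pick <- ord[, slot]
      sel <- cbind(seq_len(nv), pick)
      f_sl <- flat_norm[sel] * share[, 1]
      comp_frac[, , , slot] <- array(f_sl, dim = s)
      tx <- ty <- tz <- numeric(nv)
      ev <- matrix(0, nv, 3)
      for (i in seq_along(bundles)) {
        m <- pick == i
        if (!any(m)) next
        tx[m] <- tangents[[i]]$tx[m]
        ty[m] <- tangents[[i]]$ty[m]
        tz[m] <- tangents[[i]]$tz[m]
        ev[m, ] <- matrix(bundles[[i]]$evals, sum(m), 3, byrow = TRUE)
      }
      zero <- f_sl <= 0
      tx[zero] <- 0; ty[zero] <- 0; tz[zero] <- 0; ev[zero, ] <- 0
      comp_dir[, , , , slot] <- array(c(tx, ty, tz), dim = c(s, 3))
      comp_evals[, , , , slot] <- array(ev, dim = c(s, 3))
    }
    # renormalise compartment fractions to the WM fraction actually kept
    kept <- array(0, dim = s)
    for (slot in seq_len(K)) kept <- kept + comp_frac[, , , slot]
    scale <- array(1, dim = s)
    pos <- kept > 0
    scale[pos] <- wm[pos] / kept[pos]
    for (slot in seq_len(K))
      comp_frac[, , , slot] <- comp_frac[, , , slot] * scale
  }

  # occupancy masks: every voxel the bundle meaningfully enters. At 3 mm
  # voxels a 6 mm tube is mostly partial-volume, so a majority-occupancy
  # mask would miss half of the bundle's true extent.
  masks <- lapply(bundle_frac, function(f) f > 0.1)
  centrelines <- lapply(bundles, structure_centreline)
  names(centrelines) <- names(bundle_frac)

  structure(list(grid = grid, wm = wm, gm = gm, csf = csf,
                 head = head_frac > 0.5, head_radius_mm = head_radius_mm,
                 comp_frac = comp_frac, comp_dir = comp_dir,
                 comp_evals = comp_evals,
                 bundle_masks = masks, centrelines = centrelines,
                 csf_adc = CSF_ADC, gm_adc = GM_ADC),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom: %s, %d bundle(s): %s\n",
              paste(x$grid$shape, collapse = "x"),
              length(x$bundle_masks),
              paste(names(x$bundle_masks), collapse = ", ")))
  invisible(x)
}

#' The default phantom
#'
#' Mirror-symmetric about the mid-sagittal plane: one arc bundle per
#' hemisphere (sagittal C-shaped tracts), two straight bundles crossing at
#' 90 degrees in an axial plane, a central CSF ellipsoid (ventricle
#' analogue) and a spherical GM rind (cortex analogue). The mirror symmetry
#' gives hemispheric-asymmetry metrics a zero ground truth.
#'
#' @param n voxels per axis (isotropic grid).
#' @param vox_mm voxel size, mm.
#' @param crossing include the 90-degree crossing pair.
#' @param evals WM tensor eigenvalues, mm^2/s.
#' @return a `phantom_truth`.
#' @export
default_phantom <- function(n = 48, vox_mm = 3, crossing = TRUE,
                            evals = WM_EVALS_DEFAULT) {
  grid <- grid_geometry(rep(n, 3), vox_mm)
  half_fov <- (n - 1) / 2 * vox_mm
  sc <- half_fov / 70.5 # default geometry drawn for a 48 x 3 mm grid
  st <- list(
    bundle_arc("arc_left", center = c(-33, 0, -18) * sc, e1 = c(0, 1, 0),
               e2 = c(0, 0, 1), arc_radius = 28 * sc, radius = 6 * sc,
               theta_deg = c(20, 160), evals = evals),
    bundle_arc("arc_right", center = c(33, 0, -18) * sc, e1 = c(0, 1, 0),
               e2 = c(0, 0, 1), arc_radius = 28 * sc, radius = 6 * sc,
               theta_deg = c(20, 160), evals = evals),
    csf_ellipsoid(center = c(0, 0, -25) * sc, semiaxes = c(12, 18, 10) * sc))
  if (crossing) {
    st <- c(st, list(
      bundle_cylinder("cyl_x", center = c(0, 0, 25) * sc, axis = c(1, 0, 0),
                      radius = 6 * sc, half_length = 48 * sc, evals = evals),
      bundle_cylinder("cyl_y", center = c(0, 0, 25) * sc, axis = c(0, 1, 0),
                      radius = 6 * sc, half_length = 48 * sc, evals = evals)))
  }
  build_phantom(grid, st, head_radius_mm = 66 * sc)
}

#' Ground-truth scalar maps of a phantom
#'
#' Per-voxel composite tensor (fraction-weighted sum over fibre compartments
#' plus isotropic GM/CSF terms is deliberately NOT used here: the maps are
#' for the fibrous part only, computed from the fraction-weighted fibre
#' compartments), with FA, MD and the principal axis of the largest
#' compartment.
#'
#' @param truth a `phantom_truth`.
#' @return list with arrays `fa`, `md` and `axis` (shape x 3; unit vectors,
#'   zero where no fibre compartment exists).
#' @export
phantom_fa_md <- function(truth) {
  s <- truth$grid$shape
  nv <- prod(s)
  K <- dim(truth$comp_frac)[4]
  Dm <- matrix(0, nv, 6) # xx, yy, zz, xy, xz, yz
  ftot <- numeric(nv)
  for (k in seq_len(K)) {
    f <- as.vector(truth$comp_frac[, , , k])
    if (all(f == 0)) next
    d <- matrix(truth$comp_dir[, , , , k], nv, 3)
    ev <- matrix(truth$comp_evals[, , , , k], nv, 3)
    lam_perp <- (ev[, 2] + ev[, 3]) / 2
    # D = lam_perp I + (lam_par - lam_perp) d d^T
    dl <- ev[, 1] - lam_perp
    Dm[, 1] <- Dm[, 1] + f * (lam_perp + dl * d[, 1]^2)
    Dm[, 2] <- Dm[, 2] + f * (lam_perp + dl * d[, 2]^2)
    Dm[, 3] <- Dm[, 3] + f * (lam_perp + dl * d[, 3]^2)
    Dm[, 4] <- Dm[, 4] + f * dl * d[, 1] * d[, 2]
    Dm[, 5] <- Dm[, 5] + f * dl * d[, 1] * d[, 3]
    Dm[, 6] <- Dm[, 6] + f * dl * d[, 2] * d[, 3]
    ftot <- ftot + f
  }
  pos <- ftot > 0
  Dm[pos, ] <- Dm[pos, ] / ftot[pos]
  sc <- eigen_scalar_maps(Dm, pos)
  axis1 <- matrix(truth$comp_dir[, , , , 1], nv, 3)
  list(fa = array(sc$fa, dim = s), md = array(sc$md, dim = s),
       axis = array(axis1, dim = c(s, 3)))
}

#' Smooth multiplicative B1 bias field (synthetic)
#'
#' A Gaussian random field smoothed to `scale_mm`, rescaled so the maximum
#' relative deviation from 1 is approximately `amplitude`, and normalised to
#' mean 1 over the grid. Deterministic for a fixed seed.
#'
#' @param grid a [grid_geometry()].
#' @param amplitude peak relative deviation (0 gives a field identically 1).
#' @param scale_mm smoothness scale (Gaussian sigma), mm; at least 2 voxels.
#' @param seed RNG seed.
#' @return object of class `bias_field`: grid plus positive array `field`.
#' @export
bias_field <- function(grid, amplitude = 0.2, scale_mm = 40, seed = 1) {
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (scale_mm < 2 * grid$vox_mm)
    stop("smoothness scale must be at least 2 voxels", call. = FALSE)
  s <- grid$shape
  if (amplitude == 0) {
    f <- array(1, dim = s)
  } else {
    z <- with_seed(seed, array(stats::rnorm(prod(s)), dim = s))
    z <- gaussian_smooth3d(z, scale_mm / grid$vox_mm)
    z <- z - mean(z)
    z <- z / max(abs(z))
    f <- 1 + amplitude * z
    f <- f / mean(f)
    f[f <= 0] <- 1e-3
  }
  structure(list(grid = grid, field = f), class = "bias_field")
}
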