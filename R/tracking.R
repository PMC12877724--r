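#' Tissue fraction maps and the GM/WM interface
#'
#' Bundles the WM/GM/CSF partial-volume maps used by anatomically
#' constrained tracking, together with the derived grey-matter/white-matter
#' interface mask (voxels containing both WM and GM) used for seeding.
#'
#' @param truth a `phantom_truth`, or NULL if maps are given directly.
#' @param wm,gm,csf 3D fraction arrays in `[0, 1]` (ignored when `truth`
#'   is supplied).
#' @param grid a [grid_geometry()] (ignored when `truth` is supplied).
#' @return object of class `tissue_maps`.
#' @export
tissue_maps <- function(truth = NULL, wm = NULL, gm = NULL, csf = NULL,
                        grid = NULL) {
  if (!is.null(truth)) {
    wm <- truth$wm; gm <- truth$gm; csf <- truth$csf; grid <- truth$grid
  }
  stopifnot(!is.null(wm), !is.null(gm), !is.null(csf), !is.null(grid))
  if (max(wm + gm + csf) > 1 + 1e-6)
    stop("tissue fractions sum to more than 1", call. = FALSE)
  interface <- wm > 0 & gm > 0
  structure(list(grid = grid, wm = wm, gm = gm, csf = csf,
                 interface = interface),
            class = "tissue_maps")
}

#' Seed points on the GM/WM interface
#'
#' Samples `n` points uniformly over the interface voxels with uniform
#' jitter inside each voxel; reproducible for a fixed seed.
#'
#' @param tissue a [tissue_maps()].
#' @param n number of seed points.
#' @param seed RNG seed.
#' @return n x 3 matrix of world-mm seed positions.
#' @export
gmwmi_seeds <- function(tissue, n, seed = 1) {
  idx <- which(tissue$interface)
  if (length(idx) == 0) stop("GM/WM interface is empty", call. = FALSE)
  s <- tissue$grid$shape
  with_seed(seed, {
    pick <- idx[sample.int(length(idx), n, replace = TRUE)]
    ijk <- cbind((pick - 1) %% s[1],
                 ((pick - 1) %/% s[1]) %% s[2],
                 (pick - 1) %/% (s[1] * s[2]))
    jitter <- matrix(stats::runif(3 * n, -0.5, 0.5), n, 3)
    vox2world(tissue$grid, ijk + jitter)
  })
}

#' Anatomically constrained termination decision
#'
#' Classifies a segment endpoint by its interpolated tissue composition:
#' dominant CSF (> 0.5) rejects the whole streamline, dominant GM (> 0.5)
#' terminates and accepts it, anything else continues. Leaving the grid is
#' handled by the tracker (terminate, accept if long enough).
#'
#' @param positions n x 3 world-mm positions.
#' @param tissue a [tissue_maps()].
#' @return character vector in `{"continue", "terminate-accept", "reject"}`.
#' @export
act_check <- function(positions, tissue) {
  ijk <- world2vox(tissue$grid, positions)
  csf <- interp_trilinear(tissue$csf, ijk)
  gm <- interp_trilinear(tissue$gm, ijk)
  out <- rep("continue", nrow(rbind3(positions)))
  out[gm > 0.5] <- "terminate-accept"
  out[csf > 0.5] <- "reject"
  out
}

# trilinear interpolation of several volumes stored as a (nvox x k) matrix
interp_multi <- function(Cmat, shape, ijk) {
  ijk <- rbind3(ijk)
  d <- shape
  n <- nrow(ijk)
  p <- ijk
  i0 <- pmax(pmin(floor(p[, 1]), d[1] - 2), 0)
  j0 <- pmax(pmin(floor(p[, 2]), d[2] - 2), 0)
  k0 <- pmax(pmin(floor(p[, 3]), d[3] - 2), 0)
  fx <- p[, 1] - i0; fy <- p[, 2] - j0; fz <- p[, 3] - k0
  idx <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    acc <- acc + w * Cmat[idx(i0 + dx, j0 + dy, k0 + dz), , drop = FALSE]
  }
  acc
}

#' Streamline tractography on an fODF field
#'
#' First-order streamline propagation with bidirectional growth from each
#' seed. Deterministic mode follows the in-cone direction of maximum fODF
#' amplitude; probabilistic mode rejection-samples a direction from the
#' interpolated fODF restricted to the curvature cone, accepting amplitudes
#' above the cutoff. Termination follows the anatomical rules of
#' [act_check()] plus angle/amplitude/length rules. Each streamline uses an
#' RNG stream keyed by (global seed, seed index), so results are
#' order-independent and reproducible.
#'
#' @param fod a `fod_field`.
#' @param seeds n x 3 world-mm seed points.
#' @param mode `"probabilistic"` or `"deterministic"`.
#' @param step_mm step size (default half a voxel).
#' @param max_angle_deg curvature cap per step, degrees.
#' @param cutoff amplitude cutoff relative to the global maximum fODF
#'   amplitude (must be > 0 in probabilistic mode).
#' @param min_length_mm,max_length_mm streamline length window.
#' @param seed global RNG seed.
#' @param tissue optional [tissue_maps()] enabling anatomical constraints.
#' @param n_trials rejection-sampling trials before giving up a step.
#' @return object of class `streamline_set`: `streamlines` (list of n x 3
#'   world-mm polylines), `seed_index`, `seed_vertex` (index of the seed
#'   point within each polyline), `reason` (termination reason of the
#'   forward end), `step_mm` and `seed`. Rejected streamlines are absent.
#' @export
track <- function(fod, seeds, mode = c("probabilistic", "deterministic"),
                  step_mm = NULL, max_angle_deg = 45, cutoff = 0.1,
                  min_length_mm = 10, max_length_mm = 250, seed = 1,
                  tissue = NULL, n_trials = 1000) {
  mode <- match.arg(mode)
  grid <- fod$grid
  if (is.null(step_mm)) step_mm <- 0.5 * grid$vox_mm
  if (step_mm > grid$vox_mm)
    stop("step must not exceed the voxel size", call. = FALSE)
  if (mode == "probabilistic" && cutoff <= 0)
    stop("amplitude cutoff must be positive in probabilistic mode", call. = FALSE)
  seeds <- rbind3(seeds)
  ncoef <- sh_ncoef(fod$lmax)
  Cmat <- matrix(fod$coef, ncol = ncoef)
  dirs724 <- fibonacci_axes(724)
  B724 <- sh_basis(fod$lmax, dirs724)
  # global maximum amplitude (over fitted voxels) sets the absolute cutoff
  # and the rejection-sampling envelope
  in_fit <- which(fod$mask)
  samp <- in_fit[seq(1, length(in_fit),
                     by = max(1, floor(length(in_fit) / 2000)))]
  amax <- max(Cmat[samp, , drop = FALSE] %*% t(B724))
  cut_abs <- cutoff * amax
  cos_cone <- cos(max_angle_deg * pi / 180)
  max_steps <- ceiling(max_length_mm / step_mm)
  streamlines <- list()
  seed_idx <- integer(0)
  seed_vert <- integer(0)
  reasons <- character(0)
  fod_at <- function(pos) drop(interp_multi(Cmat, grid$shape,
                                            world2vox(grid, pos)))
  for (i in seq_len(nrow(seeds))) {
    set.seed(derive_seed(seed, paste0("streamline", i)))
    p0 <- seeds[i, ]
    cf0 <- fod_at(p0)
    amp0 <- drop(B724 %*% cf0)
    if (max(amp0) < cut_abs) next
    d0 <- dirs724[which.max(amp0), ]
    if (mode == "probabilistic") {
      d0s <- sample_fod_direction(cf0, d0, fod$lmax, -1, amax, cut_abs,
                                  n_trials, dirs724, B724)
      if (is.null(d0s)) next
      d0 <- d0s
    }
    halves <- list()
    rejected <- FALSE
    reason_fwd <- "exit"
    for (sgn in c(1, -1)) {
      pos <- p0
      d <- sgn * d0
      path <- list()
      reason <- "length"
      for (st in seq_len(max_steps)) {
        cand_pos <- pos + step_mm * d
        ijk <- world2vox(grid, cand_pos)
        if (any(ijk < 0) || any(ijk > grid$shape - 1)) { reason <- "exit"; break }
        if (!is.null(tissue)) {
          dec <- act_check(cand_pos, tissue)
          if (dec == "reject") { rejected <- TRUE; reason <- "csf-reject"; break }
          if (dec == "terminate-accept") {
            path[[length(path) + 1]] <- cand_pos
            reason <- "gm"
            break
          }
        }
        cf <- interp_multi(Cmat, grid$shape, ijk)[1, ]
        dn <- if (mode == "deterministic") {
          ct <- drop(dirs724 %*% d)
          ok <- ct > cos_cone
          if (!any(ok)) NULL else {
            a <- drop(B724[ok, , drop = FALSE] %*% cf)
            if (max(a) < cut_abs) NULL else dirs724[ok, , drop = FALSE][which.max(a), ]
          }
        } else {
          sample_fod_direction(cf, d, fod$lmax, cos_cone, amax, cut_abs,
                               n_trials, dirs724, B724)
        }
        if (is.null(dn)) { path[[length(path) + 1]] <- cand_pos
                           reason <- "amplitude"; break }
        pos <- cand_pos
        d <- dn
        path[[length(path) + 1]] <- pos
      }
      if (rejected) break
      halves[[if (sgn == 1) "fwd" else "bwd"]] <- path
      if (sgn == 1) reason_fwd <- reason
    }
    if (rejected) next
    fwd <- halves$fwd; bwd <- halves$bwd
    nb <- length(bwd); nf <- length(fwd)
    if (nb + nf < 1) next
    verts <- matrix(0, nb + 1 + nf, 3)
    if (nb > 0) for (k in seq_len(nb)) verts[nb - k + 1, ] <- bwd[[k]]
    verts[nb + 1, ] <- p0
    if (nf > 0) for (k in seq_len(nf)) verts[nb + 1 + k, ] <- fwd[[k]]
    if ((nrow(verts) - 1) * step_mm < min_length_mm) next
    streamlines[[length(streamlines) + 1]] <- verts
    seed_idx <- c(seed_idx, i)
    seed_vert <- c(seed_vert, nb + 1)
    reasons <- c(reasons, reason_fwd)
  }
  structure(list(streamlines = streamlines, seed_index = seed_idx,
                 seed_vertex = seed_vert, reason = reasons,
                 step_mm = step_mm, seed = seed, grid = grid),
            class = "streamline_set")
}

# rejection sampling of a direction from the fODF restricted to the cone
# around `d` (cos_cone = -1 samples the whole sphere)
sample_fod_direction <- function(cf, d, lmax, cos_cone, amax, cut_abs,
                                 n_trials, dirs724, B724) {
  chunk <- 25
  done <- 0
  while (done < n_trials) {
    m <- min(chunk, n_trials - done)
    ct <- stats::runif(m, max(cos_cone, -1), 1)
    phi <- stats::runif(m, 0, 2 * pi)
    st <- sqrt(pmax(0, 1 - ct^2))
    local <- cbind(st * cos(phi), st * sin(phi), ct)
    # rotate local z onto d
    cand <- rotate_z_to(local, d)
    a <- drop(sh_basis(lmax, cand) %*% cf)
    u <- stats::runif(m, 0, amax)
    ok <- which(a >= cut_abs & u < a)
    if (length(ok) > 0) return(cand[ok[1], ])
    done <- done + m
  }
  NULL
}

rotate_z_to <- function(points, d) {
  d <- d / sqrt(sum(d^2))
  if (abs(d[3]) > 0.999999) {
    if (d[3] > 0) return(points)
    return(points %*% diag(c(1, -1, -1)))
  }
  ax <- cross3(c(0, 0, 1), d)
  s <- sqrt(sum(ax^2)); ax <- ax / s
  ang <- acos(d[3])
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  points %*% t(R)
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("streamline set: %d streamlines, step %.2f mm\n",
              length(x$streamlines), x$step_mm))
  invisible(x)
}

streamline_lengths <- function(sl) {
  vapply(sl$streamlines, function(v) (nrow(v) - 1) * sl$step_mm, 0)
}

#' Filter streamlines by inclusion / exclusion regions
#'
#' Keeps only streamlines that intersect every inclusion ROI. Exclusion
#' regions either discard whole streamlines or trim them: traversal from the
#' seed outwards in both directions stops just before the first vertex
#' inside any exclusion ROI, and the remaining (seed-side) portion is kept
#' if it is still at least `min_length_mm` long.
#'
#' @param sl a `streamline_set`.
#' @param include,exclude lists of logical 3D arrays on the tracking grid.
#' @param exclude_mode `"discard"` or `"trim"`.
#' @param min_length_mm minimum retained length after trimming.
#' @return the filtered `streamline_set`.
#' @export
roi_filter <- function(sl, include = list(), exclude = list(),
                       exclude_mode = c("discard", "trim"),
                       min_length_mm = 10) {
  exclude_mode <- match.arg(exclude_mode)
  grid <- sl$grid
  in_roi <- function(verts, roi) {
    ijk <- round(world2vox(grid, verts))
    inside <- ijk[, 1] >= 0 & ijk[, 1] < grid$shape[1] &
              ijk[, 2] >= 0 & ijk[, 2] < grid$shape[2] &
              ijk[, 3] >= 0 & ijk[, 3] < grid$shape[3]
    hit <- rep(FALSE, nrow(verts))
    hit[inside] <- roi[1 + ijk[inside, 1] + grid$shape[1] *
                         (ijk[inside, 2] + grid$shape[2] * ijk[inside, 3])]
    hit
  }
  keep <- rep(TRUE, length(sl$streamlines))
  out_streamlines <- sl$streamlines
  out_seed_vertex <- sl$seed_vertex
  for (i in seq_along(sl$streamlines)) {
    v <- sl$streamlines[[i]]
    for (roi in include)
      if (!any(in_roi(v, roi))) { keep[i] <- FALSE; break }
    if (!keep[i]) next
    if (length(exclude) > 0) {
      hit <- rep(FALSE, nrow(v))
      for (roi in exclude) hit <- hit | in_roi(v, roi)
      if (any(hit)) {
        if (exclude_mode == "discard") { keep[i] <- FALSE; next }
        sv <- sl$seed_vertex[i]
        if (hit[sv]) { keep[i] <- FALSE; next }
        lo <- sv; hi <- sv
        while (lo > 1 && !hit[lo - 1]) lo <- lo - 1
        while (hi < nrow(v) && !hit[hi + 1]) hi <- hi + 1
        v2 <- v[lo:hi, , drop = FALSE]
        if ((nrow(v2) - 1) * sl$step_mm < min_length_mm) { keep[i] <- FALSE; next }
        out_streamlines[[i]] <- v2
        out_seed_vertex[i] <- sv - lo + 1
      }
    }
  }
  structure(list(streamlines = out_streamlines[keep],
                 seed_index = sl$seed_index[keep],
                 seed_vertex = out_seed_vertex[keep],
                 reason = sl$reason[keep],
                 step_mm = sl$step_mm, seed = sl$seed, grid = sl$grid),
            class = "streamline_set")
}

#' Track-density map
#'
#' Counts per-voxel streamline visitations; each streamline contributes at
#' most 1 per voxel, so the map total equals the sum of per-streamline
#' unique-voxel visits.
#'
#' @param sl a `streamline_set`.
#' @param grid target [grid_geometry()] (defaults to the tracking grid).
#' @return 3D array of counts.
#' @export
track_density <- function(sl, grid = NULL) {
  if (is.null(grid)) grid <- sl$grid
  dens <- array(0, dim = grid$shape)
  for (v in sl$streamlines) {
    ijk <- round(world2vox(grid, v))
    inside <- ijk[, 1] >= 0 & ijk[, 1] < grid$shape[1] &
              ijk[, 2] >= 0 & ijk[, 2] < grid$shape[2] &
              ijk[, 3] >= 0 & ijk[, 3] < grid$shape[3]
    ijk <- ijk[inside, , drop = FALSE]
    if (nrow(ijk) == 0) next
    lin <- unique(1 + ijk[, 1] + grid$shape[1] *
                    (ijk[, 2] + grid$shape[2] * ijk[, 3]))
    dens[lin] <- dens[lin] + 1
  }
  dens
}
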