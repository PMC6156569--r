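#' Voxelwise Funk-Radon transform of a scattering volume
#'
#' Applies the analytic coefficient-space Funk-Radon transform
#' ([funk_radon_sh()]) to every voxel; grid metadata is preserved. Girdle
#' (plate-like) scattering concentrated in the plane orthogonal to a fiber
#' becomes, after the transform, a profile peaked along the fiber axis.
#'
#' @param volume A [scattering_volume()].
#' @return A [scattering_volume()] of transformed coefficients.
#' @export
funk_radon_volume <- function(volume) {
  stopifnot(inherits(volume, "scattering_volume"))
  scale <- funk_radon_eigenvalues(volume$basis)
  coefs <- volume$coefficients
  for (k in seq_along(scale)) {
    coefs[, , , k] <- coefs[, , , k] * scale[k]
  }
  scattering_volume(coefs, volume$basis, volume$spacing, volume$origin)
}

#' Anisotropy index of a scattering profile
#'
#' Ratio of the anisotropic (degree >= 2) coefficient energy to the total:
#' 0 for an isotropic profile, approaching 1 as the spherical mean vanishes
#' relative to the structure. Used as a masking proxy for strongly oriented
#' (white-matter-like) voxels.
#'
#' @param coeffs An [sh_coefficients()], or a numeric coefficient vector
#'   with `basis`.
#' @param basis Required if `coeffs` is a bare vector.
#' @return A value in `[0, 1]`.
#' @export
anisotropy_index <- function(coeffs, basis = NULL) {
  if (inherits(coeffs, "sh_coefficients")) {
    basis <- coeffs$basis
    v <- coeffs$values
  } else {
    stopifnot(inherits(basis, "sh_basis"))
    v <- as.numeric(coeffs)
  }
  hi <- basis$degrees$l >= 2
  sqrt(sum(v[hi]^2)) / (sqrt(sum(v^2)) + .Machine$double.eps)
}

# max over 1-ring neighbors, computed column-parallel for a nvert x n value
# matrix (vectorized: one pmax sweep per vertex, not one call per entry)
.neighbor_max <- function(V, grid) {
  out <- matrix(-Inf, nrow(V), ncol(V))
  for (i in seq_len(nrow(V))) {
    nb <- grid$neighbors[[i]]
    if (length(nb) == 0) next
    m <- V[nb[1], ]
    for (j in nb[-1]) m <- pmax(m, V[j, ])
    out[i, ] <- m
  }
  out
}

.empty_peaks <- list(directions = matrix(numeric(0), 0, 3),
                     magnitudes = numeric(0))

# greedy angular suppression + canonicalization of candidate peak vertices
.select_peaks <- function(idx, values, grid, relative_threshold,
                          min_separation_deg) {
  vmax <- max(values)
  vmin <- min(values)
  # flat-profile guard: isotropic voxels have no local structure
  if (!is.finite(vmax) || (vmax - vmin) < 1e-6 * abs(vmax) || vmax <= 0) {
    return(.empty_peaks)
  }
  idx <- idx[values[idx] >= relative_threshold * vmax]
  if (length(idx) == 0) return(.empty_peaks)
  idx <- idx[order(values[idx], decreasing = TRUE)]
  min_sep <- min_separation_deg * pi / 180
  kept <- integer(0)
  for (i in idx) {
    if (length(kept) > 0) {
      ang <- acos(pmin(1, abs(grid$directions[kept, , drop = FALSE] %*%
                                grid$directions[i, ])))
      if (any(ang < min_sep)) next
    }
    kept <- c(kept, i)
  }
  list(directions = canonical_direction(
         grid$directions[kept, , drop = FALSE]),
       magnitudes = values[kept])
}

.peaks_from_values <- function(values, grid, relative_threshold,
                               min_separation_deg) {
  nbmax <- .neighbor_max(cbind(values), grid)[, 1]
  .select_peaks(which(values >= nbmax), values, grid, relative_threshold,
                min_separation_deg)
}

#' Detect orientation peaks of a Funk-Radon profile on a sphere grid
#'
#' Evaluates the (already Funk-Radon-transformed) expansion on the grid; a
#' vertex is a peak if its value is >= all 1-ring neighbors. Peaks below
#' `relative_threshold` times the global maximum are dropped, and weaker
#' peaks within `min_separation_deg` of a stronger one are greedily
#' suppressed. Flat profiles (max - min < 1e-6 of the max) report no peaks.
#'
#' @param frt_coeffs [sh_coefficients()] of the Funk-Radon-transformed
#'   profile.
#' @param grid A hemisphere [icosphere()] grid (antipodes collapsed).
#' @param relative_threshold In `(0, 1]`.
#' @param min_separation_deg Minimum angular separation between peaks.
#' @return List of `directions` (n x 3, canonical antipodal
#'   representatives, sorted by descending magnitude) and `magnitudes`
#'   (Funk-Radon values).
#' @export
extract_peaks <- function(frt_coeffs, grid, relative_threshold = 0.5,
                          min_separation_deg = 15) {
  stopifnot(inherits(frt_coeffs, "sh_coefficients"),
            inherits(grid, "sphere_grid"),
            relative_threshold > 0, relative_threshold <= 1)
  if (nrow(grid$directions) == 0) {
    .axdt_stop("axdt_invalid_argument", "empty sphere grid")
  }
  values <- evaluate_sh(frt_coeffs, grid$directions)
  .peaks_from_values(values, grid, relative_threshold, min_separation_deg)
}

#' Per-voxel principal fiber orientations of a Funk-Radon volume
#'
#' Runs peak detection in every voxel of a Funk-Radon-transformed volume.
#' Voxels whose peak magnitude falls below the magnitude threshold, or
#' whose anisotropy index falls below the anisotropy threshold, get an
#' empty peak list; elsewhere the principal (largest-magnitude) peak forms
#' the vector field used for tracking. The magnitude threshold stands in
#' for masking by scattering strength: by default it is a quantile of the
#' per-voxel maximum Funk-Radon values so that only the most strongly
#' scattering, oriented voxels are kept.
#'
#' @param frt_volume A Funk-Radon-transformed [scattering_volume()].
#' @param grid A hemisphere [icosphere()] grid.
#' @param relative_threshold,min_separation_deg Passed to peak detection.
#' @param magnitude_threshold Absolute magnitude cut; if `NULL`, computed as
#'   `magnitude_quantile` of the positive per-voxel maxima.
#' @param magnitude_quantile Quantile used when `magnitude_threshold` is
#'   `NULL` (default 0.7).
#' @param anisotropy_threshold Minimum [anisotropy_index()] of the original
#'   (pre-transform) profile for a voxel to carry orientations.
#' @return Object of class `orientation_field`: `principal` (nvox x 3
#'   matrix, `NA` rows where empty), `magnitude`, `anisotropy` vectors,
#'   `peaks` (list per voxel), grid metadata (`dims`, `spacing`, `origin`)
#'   and the resolved thresholds.
#' @export
principal_orientation_field <- function(frt_volume, grid = icosphere(4, TRUE),
                                        relative_threshold = 0.5,
                                        min_separation_deg = 15,
                                        magnitude_threshold = NULL,
                                        magnitude_quantile = 0.7,
                                        anisotropy_threshold = 0.05) {
  stopifnot(inherits(frt_volume, "scattering_volume"),
            inherits(grid, "sphere_grid"))
  nvox <- prod(frt_volume$dims)
  K <- frt_volume$basis$size
  cmat <- matrix(frt_volume$coefficients, nvox, K)
  B <- sh_design_matrix(frt_volume$basis, grid$directions)  # nvert x K
  vals <- B %*% t(cmat)                                     # nvert x nvox
  vox_max <- apply(vals, 2, max)
  hi <- frt_volume$basis$degrees$l >= 2
  aniso <- sqrt(rowSums(cmat[, hi, drop = FALSE]^2)) /
    (sqrt(rowSums(cmat^2)) + .Machine$double.eps)
  if (is.null(magnitude_threshold)) {
    pos <- vox_max[vox_max > 0]
    magnitude_threshold <- if (length(pos)) {
      as.numeric(quantile(pos, magnitude_quantile))
    } else {
      Inf
    }
  }
  principal <- matrix(NA_real_, nvox, 3)
  magnitude <- rep(NA_real_, nvox)
  peaks <- vector("list", nvox)
  candidates <- which(vox_max >= magnitude_threshold &
                        aniso >= anisotropy_threshold)
  if (length(candidates) > 0) {
    V <- vals[, candidates, drop = FALSE]
    is_peak <- V >= .neighbor_max(V, grid)
    for (j in seq_along(candidates)) {
      v <- candidates[j]
      pk <- .select_peaks(which(is_peak[, j]), V[, j], grid,
                          relative_threshold, min_separation_deg)
      peaks[[v]] <- pk
      if (nrow(pk$directions) > 0) {
        principal[v, ] <- pk$directions[1, ]
        magnitude[v] <- pk$magnitudes[1]
      }
    }
  }
  for (v in setdiff(seq_len(nvox), candidates)) peaks[[v]] <- .empty_peaks
  structure(list(principal = principal, magnitude = magnitude,
                 anisotropy = aniso, peaks = peaks,
                 dims = frt_volume$dims, spacing = frt_volume$spacing,
                 origin = frt_volume$origin,
                 thresholds = list(relative = relative_threshold,
                                   min_separation_deg = min_separation_deg,
                                   magnitude = magnitude_threshold,
                                   anisotropy = anisotropy_threshold)),
            class = "orientation_field")
}

.world_to_frac <- function(field, pt) {
  (pt - field$origin) / field$spacing - 0.5
}

# Trilinear interpolation of the sign-ambiguous principal-orientation field:
# each corner vector is sign-aligned with the incoming direction before
# averaging; corners without orientation contribute nothing. Returns the
# (unnormalized) mean vector and interpolated magnitude.
.interp_orientation <- function(field, pt, ref_dir) {
  f <- .world_to_frac(field, pt)
  i0 <- floor(f)
  w1 <- f - i0
  acc <- c(0, 0, 0)
  mag <- 0
  wtot <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ijk <- i0 + c(dx, dy, dz)
    if (any(ijk < 0) || any(ijk >= field$dims)) next
    w <- prod(ifelse(c(dx, dy, dz) == 1, w1, 1 - w1))
    if (w == 0) next
    v <- ijk[1] + field$dims[1] * (ijk[2] + field$dims[2] * ijk[3]) + 1
    d <- field$principal[v, ]
    if (any(is.na(d))) next
    if (sum(d * ref_dir) < 0) d <- -d
    acc <- acc + w * d
    mag <- mag + w * field$magnitude[v]
    wtot <- wtot + w
  }
  # require majority interpolation support: without this the field would be
  # extrapolated up to a full voxel beyond the oriented region's edge
  if (wtot < 0.5) return(NULL)
  list(dir = acc, magnitude = mag / wtot)
}

.track_half <- function(field, seed_pt, dir0, step_mm, max_angle_deg,
                        min_magnitude, max_steps) {
  pts <- list(seed_pt)
  d_prev <- dir0
  reason <- "max-steps"
  cos_max <- cos(max_angle_deg * pi / 180)
  pt <- seed_pt
  for (i in seq_len(max_steps)) {
    o <- .interp_orientation(field, pt, d_prev)
    if (is.null(o) || sqrt(sum(o$dir^2)) < 1e-12) {
      f <- .world_to_frac(field, pt)
      reason <- if (any(f < -0.5) || any(f > field$dims - 0.5))
        "left-volume" else "low-magnitude"
      break
    }
    if (o$magnitude < min_magnitude) { reason <- "low-magnitude"; break }
    d <- o$dir / sqrt(sum(o$dir^2))
    if (sum(d * d_prev) < cos_max) { reason <- "high-curvature"; break }
    pt_new <- pt + step_mm * d
    f <- .world_to_frac(field, pt_new)
    if (any(f < -0.5) || any(f > field$dims - 0.5)) { reason <- "left-volume"; break }
    # only emit points with interpolation support, so streamlines end at
    # the oriented region instead of overshooting by a step
    if (is.null(.interp_orientation(field, pt_new, d))) {
      reason <- "low-magnitude"
      break
    }
    pts[[length(pts) + 1L]] <- pt_new
    pt <- pt_new
    d_prev <- d
  }
  list(points = do.call(rbind, pts), reason = reason)
}

#' Deterministic streamline tractography through an orientation field
#'
#' Bidirectional Euler integration of the principal-orientation vector
#' field from each seed. Orientations are sign-ambiguous; at every step the
#' interpolated orientation is sign-aligned with the incoming direction
#' before use, and the two half-tracks (started along +/- the seed
#' orientation) are concatenated. A streamline terminates on leaving the
#' volume, on interpolated magnitude below `min_magnitude`, on a turning
#' angle above `max_angle_deg` per step, or at `max_steps`.
#'
#' @param field An [principal_orientation_field()] result.
#' @param seeds n x 3 matrix of seed points (world mm), inside the grid.
#' @param step_mm Integration step (mm), > 0.
#' @param max_angle_deg Maximum turning angle per step (degrees).
#' @param min_magnitude Minimum interpolated peak magnitude to continue.
#' @param max_steps Maximum steps per half-track.
#' @return List of streamlines, each with `points` (m x 3 world
#'   coordinates) and `reason` (termination reasons of the two half-tracks).
#' @export
track_streamlines <- function(field, seeds, step_mm = NULL,
                              max_angle_deg = 60, min_magnitude = 0,
                              max_steps = 1000) {
  stopifnot(inherits(field, "orientation_field"))
  seeds <- rbind(seeds)
  if (is.null(step_mm)) step_mm <- 0.5 * field$spacing
  stopifnot(step_mm > 0)
  lapply(seq_len(nrow(seeds)), function(i) {
    seed <- seeds[i, ]
    f <- .world_to_frac(field, seed)
    if (any(f < -0.5) || any(f > field$dims - 0.5)) {
      .axdt_stop("axdt_invalid_argument", "seed outside the volume")
    }
    # reference direction for the sign alignment at the seed: the nearest
    # voxel's principal orientation (an arbitrary reference could be
    # near-orthogonal to the local fiber and cancel the aligned mean)
    ijk <- pmin(pmax(round(f), 0), field$dims - 1)
    v <- ijk[1] + field$dims[1] * (ijk[2] + field$dims[2] * ijk[3]) + 1
    ref <- field$principal[v, ]
    ref <- if (any(is.na(ref))) c(1, 0, 0) else canonical_direction(ref)
    o <- .interp_orientation(field, seed, ref)
    if (is.null(o) || sqrt(sum(o$dir^2)) < 1e-12 ||
        o$magnitude < min_magnitude) {
      return(list(points = rbind(seed, seed), reason = "low-magnitude"))
    }
    d0 <- o$dir / sqrt(sum(o$dir^2))
    fwd <- .track_half(field, seed, d0, step_mm, max_angle_deg,
                       min_magnitude, max_steps)
    bwd <- .track_half(field, seed, -d0, step_mm, max_angle_deg,
                       min_magnitude, max_steps)
    pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points)))[-nrow(bwd$points)],
                            , drop = FALSE],
                 fwd$points)
    if (nrow(pts) < 2) pts <- rbind(pts, pts)
    list(points = pts, reason = paste(bwd$reason, fwd$reason, sep = "|"))
  })
}
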