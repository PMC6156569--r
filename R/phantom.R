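#' Girdle (plate-like) scattering profile of a thin fiber
#'
#' A thin fiber scatters X-rays predominantly orthogonal to its axis, so
#' its scattering profile is concentrated on the great circle orthogonal to
#' the fiber direction `f` ("plate-like"). The profile is a Watson-type
#' girdle density
#' `eta(e) = strength * N(kappa) * exp(-kappa * <e, f>^2)`,
#' with `N(kappa)` normalizing the spherical mean to 1 so that `strength`
#' is the mean scattering per mm. The density is maximal on the girdle
#' plane and minimal at `+/- f`; `kappa = 0` is the isotropic limit. The
#' profile is fitted to the requested band-limited basis on a
#' subdivision-4 icosphere.
#'
#' @param fiber_direction Unit 3-vector `f`.
#' @param strength Mean scattering strength per mm (>= 0).
#' @param kappa Girdle concentration (>= 0, default 5).
#' @param basis An [sh_basis()].
#' @return An [sh_coefficients()].
#' @export
girdle_profile_sh <- function(fiber_direction, strength = 1, kappa = 5,
                              basis = sh_basis(4)) {
  f <- drop(.check_unit_directions(fiber_direction))
  stopifnot(strength >= 0, kappa >= 0, is.finite(kappa))
  if (kappa == 0) {
    v <- numeric(basis$size)
    v[1] <- strength * sqrt(4 * pi)
    return(sh_coefficients(v, basis))
  }
  # spherical mean of exp(-kappa t^2): int_0^1 exp(-kappa t^2) dt
  mean_val <- sqrt(pi / (4 * kappa)) * pracma::erf(sqrt(kappa))
  grid <- icosphere(4)
  t2 <- drop(grid$directions %*% f)^2
  vals <- strength * exp(-kappa * t2) / mean_val
  fit_sh(grid$directions, vals, basis)
}

.grid_centers <- function(dims, spacing, origin) {
  cx <- origin[1] + (seq_len(dims[1]) - 0.5) * spacing
  cy <- origin[2] + (seq_len(dims[2]) - 0.5) * spacing
  cz <- origin[3] + (seq_len(dims[3]) - 0.5) * spacing
  list(x = cx, y = cy, z = cz,
       all = cbind(rep(cx, times = dims[2] * dims[3]),
                   rep(rep(cy, each = dims[1]), times = dims[3]),
                   rep(cz, each = dims[1] * dims[2])))
}

#' Specification of a synthetic fiber phantom
#'
#' Describes a voxel grid plus a list of fiber primitives standing in for
#' aligned axon bundles: each primitive assigns girdle scattering along its
#' local tangent to the voxels it covers.
#'
#' @param dims Length-3 grid shape (or scalar for a cube).
#' @param spacing Voxel spacing in mm (default 0.5, a typical effective
#'   voxel size for bench-top dark-field tomography of brain specimens).
#' @param primitives List of primitive lists, each with `type`
#'   (`"straight-bundle"`, `"helix"` or `"crossing-pair"`) and geometric
#'   parameters in mm (see Details).
#' @param background_isotropic_strength Isotropic scattering of non-fiber
#'   voxels (>= 0).
#'
#' @details Primitive fields (all lengths in mm): `straight-bundle`:
#' `center`, `axis`, `radius`, optional `half_length`; `helix`: `center`,
#' `radius` (helix radius), `pitch` (z advance per turn), `tube_radius`,
#' optional `turns` (default 1); `crossing-pair`: two straight bundles
#' `axis1`/`axis2`, shared `center` and `radius`; `ball`: `center`,
#' `radius`, an isotropically scattering sphere (no fiber direction). All
#' accept `scattering_strength` (per mm, default 1); the fibrous types also
#' accept `girdle_concentration` (kappa, default 5).
#' @return Object of class `fiber_phantom_spec`.
#' @export
fiber_phantom_spec <- function(dims, spacing = 0.5, primitives = list(),
                               background_isotropic_strength = 0) {
  if (length(dims) == 1) dims <- rep(dims, 3)
  stopifnot(spacing > 0, background_isotropic_strength >= 0)
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 primitives = primitives,
                 background = as.numeric(background_isotropic_strength)),
            class = "fiber_phantom_spec")
}

# voxel membership + unit tangents of one primitive; centers is nvox x 3
.primitive_tangents <- function(prim, centers) {
  type <- prim$type
  if (type == "straight-bundle" || type == "crossing-pair") {
    axes <- if (type == "straight-bundle") list(prim$axis) else
      list(prim$axis1, prim$axis2)
    out <- lapply(axes, function(a) {
      a <- a / sqrt(sum(a^2))
      rel <- sweep(centers, 2, prim$center)
      along <- drop(rel %*% a)
      radial2 <- rowSums(rel^2) - along^2
      inside <- radial2 <= prim$radius^2
      if (!is.null(prim$half_length)) {
        inside <- inside & abs(along) <= prim$half_length
      }
      list(inside = inside,
           tangents = matrix(a, sum(inside), 3, byrow = TRUE))
    })
    return(out)
  }
  if (type == "ball") {
    rel <- sweep(centers, 2, prim$center)
    inside <- rowSums(rel^2) <= prim$radius^2
    return(list(list(inside = inside, tangents = NULL)))
  }
  if (type == "helix") {
    turns <- if (is.null(prim$turns)) 1 else prim$turns
    nsamp <- max(200L, ceiling(400 * turns))
    th <- seq(-pi * turns, pi * turns, length.out = nsamp)
    curve <- cbind(prim$center[1] + prim$radius * cos(th),
                   prim$center[2] + prim$radius * sin(th),
                   prim$center[3] + prim$pitch * th / (2 * pi))
    # nearest curve sample per voxel
    d2 <- outer(rowSums(centers^2), rowSums(curve^2), `+`) -
      2 * centers %*% t(curve)
    jmin <- max.col(-d2)
    dmin2 <- d2[cbind(seq_len(nrow(centers)), jmin)]
    inside <- dmin2 <= prim$tube_radius^2
    thv <- th[jmin[inside]]
    tang <- cbind(-prim$radius * sin(thv), prim$radius * cos(thv),
                  rep(prim$pitch / (2 * pi), length(thv)))
    tang <- tang / sqrt(rowSums(tang^2))
    return(list(list(inside = inside, tangents = tang)))
  }
  .axdt_stop("axdt_invalid_argument", "unknown primitive type '%s'", type)
}

#' Build a ground-truth scattering volume from a phantom specification
#'
#' Voxels covered by a primitive receive a girdle profile along the local
#' fiber tangent (straight bundles: the axis; helices: the analytic
#' tangent; crossings: the sum of two girdles — overlaps are summed);
#' background voxels receive isotropic scattering. Deterministic.
#'
#' @param spec A [fiber_phantom_spec()].
#' @param basis An [sh_basis()] (default degree 4).
#' @return List with `volume` (a [scattering_volume()]), `directions`
#'   (list per voxel of true fiber directions, canonical representatives),
#'   `mask` (logical 3D array of in-fiber voxels) and `helix_params` when a
#'   helix is present.
#' @export
build_phantom <- function(spec, basis = sh_basis(4)) {
  stopifnot(inherits(spec, "fiber_phantom_spec"))
  dims <- spec$dims
  origin <- -dims * spec$spacing / 2
  centers <- .grid_centers(dims, spec$spacing, origin)$all
  nvox <- nrow(centers)
  K <- basis$size
  cmat <- matrix(0, nvox, K)
  if (spec$background > 0) {
    cmat[, 1] <- spec$background * sqrt(4 * pi)
  }
  truth <- vector("list", nvox)
  mask <- rep(FALSE, nvox)
  for (prim in spec$primitives) {
    strength <- if (is.null(prim$scattering_strength)) 1 else
      prim$scattering_strength
    kappa <- if (is.null(prim$girdle_concentration)) 5 else
      prim$girdle_concentration
    for (branch in .primitive_tangents(prim, centers)) {
      idx <- which(branch$inside)
      if (length(idx) == 0) next
      if (is.null(branch$tangents)) {
        # isotropic region (ball): spherical-mean contribution only
        cmat[idx, 1] <- cmat[idx, 1] + strength * sqrt(4 * pi)
        next
      }
      tang <- branch$tangents
      # cache girdle fits per unique tangent (straight bundles share one)
      key <- apply(round(tang, 10), 1, paste, collapse = ",")
      for (u in unique(key)) {
        sel <- idx[key == u]
        f <- tang[match(u, key), ]
        prof <- girdle_profile_sh(f, strength, kappa, basis)
        cmat[sel, ] <- cmat[sel, , drop = FALSE] +
          matrix(prof$values, length(sel), K, byrow = TRUE)
      }
      mask[idx] <- TRUE
      canon <- canonical_direction(tang)
      for (j in seq_along(idx)) {
        truth[[idx[j]]] <- rbind(truth[[idx[j]]],
                                 rbind(canon)[j, , drop = FALSE])
      }
    }
  }
  volume <- scattering_volume(array(cmat, c(dims, K)), basis,
                              spec$spacing, origin)
  list(volume = volume, directions = truth,
       mask = array(mask, dims), spec = spec)
}

#' One-call synthetic acquisition fixtures
#'
#' Builds a named phantom, a quasi-uniform Euler-cradle protocol and a
#' simulated dark-field sinogram. Defaults emulate the study conditions of
#' a bench-top dark-field scan of a fibrous specimen: 0.5 mm voxels,
#' girdle concentration 5, 80 Euler orientations with staggered tomographic
#' angles (hemisphere coverage under 0.4 rad), a detector oversampling the
#' grid at half-voxel pitch (as bench detectors resolve finer than the
#' reconstructed voxels), and multiplicative log-normal noise of the
#' requested sigma.
#' Fully deterministic given `seed`.
#'
#' @param name One of `"straight"`, `"helix"`, `"crossing"`, `"isotropic"`.
#' @param size Cubic grid size in voxels (default 32).
#' @param seed Integer seed driving the protocol azimuth and the noise.
#' @param noise_sigma Log-domain noise level (default 0).
#' @param max_degree SH degree of the ground-truth volume (default 2,
#'   matching what the squared-cosine kernel can observe).
#' @param n_euler_poses,n_tomo_angles Protocol size (defaults 80 x 1; the
#'   80 Euler targets cover the hemisphere to under 0.4 rad and the
#'   staggered tomo angles spread the view directions).
#' @param detector Optional [detector_spec()]; by default an odd-sized
#'   detector oversampling the grid at half-voxel pitch.
#' @return List with `phantom` (see [build_phantom()]), `volume`,
#'   `protocol`, `sinogram` (transmission domain) and `truth`
#'   (directions + mask).
#' @export
make_fixture <- function(name, size = 32, seed = 1, noise_sigma = 0,
                         max_degree = 2, n_euler_poses = 80,
                         n_tomo_angles = 1, detector = NULL) {
  basis <- sh_basis(max_degree)
  spacing <- 0.5
  half <- size * spacing / 2
  spec <- switch(
    name,
    straight = fiber_phantom_spec(size, spacing, list(
      list(type = "straight-bundle", center = c(0, 0, 0), axis = c(1, 0, 0),
           radius = 0.22 * size * spacing, scattering_strength = 0.15,
           girdle_concentration = 5))),
    helix = fiber_phantom_spec(size, spacing, list(
      list(type = "helix", center = c(0, 0, 0),
           radius = 0.25 * size * spacing, pitch = 0.4 * size * spacing,
           tube_radius = 0.09 * size * spacing, turns = 1,
           scattering_strength = 0.15, girdle_concentration = 5))),
    crossing = fiber_phantom_spec(size, spacing, list(
      list(type = "crossing-pair", center = c(0, 0, 0),
           axis1 = c(1, 0, 0), axis2 = c(0, 1, 0),
           radius = 0.15 * size * spacing, scattering_strength = 0.15,
           girdle_concentration = 5))),
    isotropic = fiber_phantom_spec(size, spacing, list(
      list(type = "ball", center = c(0, 0, 0),
           radius = 0.35 * size * spacing, scattering_strength = 0.08))),
    .axdt_stop("axdt_invalid_argument", "unknown fixture '%s'", name)
  )
  phantom <- build_phantom(spec, basis)
  if (is.null(detector)) {
    det_n <- 3L * size + 1L  # odd, so one ray passes through the exact center
    detector <- detector_spec(det_n, det_n, spacing / 2)
  }
  protocol <- build_protocol(n_euler_poses, n_tomo_angles, detector,
                             seed = seed)
  sinogram <- simulate_darkfield(phantom$volume, protocol, noise_sigma,
                                 seed = seed)
  list(phantom = phantom, volume = phantom$volume, protocol = protocol,
       sinogram = sinogram,
       truth = list(directions = phantom$directions, mask = phantom$mask))
}

#' Mean angular error of an orientation field against phantom truth
#'
#' Angles are computed modulo the antipodal ambiguity
#' (`min(theta, pi - theta)`); for voxels with several true directions
#' (crossings) the closest is used. Voxels without an extracted principal
#' orientation count as 90 degrees.
#'
#' @param field An [principal_orientation_field()] result.
#' @param truth The `truth` entry of [make_fixture()].
#' @return List with `mean_deg`, `median_deg`, per-voxel `errors_deg` and
#'   `n_extracted`.
#' @export
orientation_error <- function(field, truth) {
  idx <- which(as.logical(truth$mask))
  errs <- vapply(idx, function(v) {
    est <- field$principal[v, ]
    if (any(is.na(est))) return(90)
    td <- truth$directions[[v]]
    cosang <- abs(td %*% est)
    min(acos(pmin(1, cosang))) * 180 / pi
  }, numeric(1))
  list(mean_deg = mean(errs), median_deg = stats::median(errs),
       errors_deg = errs,
       n_extracted = sum(!is.na(field$principal[idx, 1])))
}
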