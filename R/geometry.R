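#' Grating-interferometer sensitivity direction
#'
#' The interferometer is insensitive to scattering along the grating bars
#' `t`; the dark-field signal is driven by scattering components along the
#' in-detector-plane direction orthogonal to both the beam `l` and the bars,
#' `s = (l x t) / ||l x t||`. `{t, s, l}` forms a right-handed orthonormal
#' triple.
#'
#' @param l Beam direction, unit 3-vector.
#' @param t Grating orientation (along the bars), unit 3-vector.
#' @return Unit 3-vector `s`.
#' @export
sensitivity_direction <- function(l, t) {
  l <- drop(.check_unit_directions(l))
  t <- drop(.check_unit_directions(t))
  s <- c(l[2] * t[3] - l[3] * t[2],
         l[3] * t[1] - l[1] * t[3],
         l[1] * t[2] - l[2] * t[1])
  n <- sqrt(sum(s^2))
  if (n < 1e-8) {
    .axdt_stop("axdt_degenerate_frame",
               "beam and grating directions are (near-)parallel")
  }
  s / n
}

.rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}
.rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' Sample rotation of an Euler-cradle pose
#'
#' The Euler cradle orients the sample by extrinsic Z-Y-Z rotations
#' `(alpha, beta, gamma)`; the tomographic stage then turns it about the
#' laboratory vertical axis (the y axis, which coincides with the default
#' sensitivity direction). The composed rotation maps sample-frame vectors
#' to the laboratory frame:
#' `R = R_tomo * R_z(alpha) * R_y(beta) * R_z(gamma)`.
#'
#' @param euler_angles Length-3 numeric `(alpha, beta, gamma)` in radians.
#' @param tomo_angle Tomographic angle in radians about the lab y axis.
#' @return 3 x 3 rotation matrix.
#' @export
pose_rotation <- function(euler_angles, tomo_angle = 0) {
  stopifnot(length(euler_angles) == 3, all(is.finite(euler_angles)),
            is.finite(tomo_angle))
  ct <- cos(tomo_angle); st <- sin(tomo_angle)
  r_tomo <- matrix(c(ct, 0, -st, 0, 1, 0, st, 0, ct), 3, 3)
  r_tomo %*% .rot_z(euler_angles[1]) %*% .rot_y(euler_angles[2]) %*%
    .rot_z(euler_angles[3])
}

#' A measurement pose
#'
#' @param euler_angles `(alpha, beta, gamma)` radians, extrinsic Z-Y-Z.
#' @param tomo_angle Tomographic angle (radians) about the lab y axis.
#' @return Object of class `axdt_pose` with the derived `rotation`.
#' @export
pose <- function(euler_angles = c(0, 0, 0), tomo_angle = 0) {
  R <- pose_rotation(euler_angles, tomo_angle)
  structure(list(euler_angles = as.numeric(euler_angles),
                 tomo_angle = as.numeric(tomo_angle), rotation = R),
            class = "axdt_pose")
}

#' Laboratory grating frame
#'
#' The default matches a three-grating bench with a horizontal beam along z
#' and vertical grating bars along x, so the sensitivity direction is the
#' lab y axis. The frame is fixed in the laboratory; the sample moves.
#'
#' @param l Beam direction (unit).
#' @param t Grating orientation (unit, orthogonal to `l`).
#' @return Object of class `grating_frame` with fields `l`, `t`, `s`.
#' @export
grating_frame <- function(l = c(0, 0, 1), t = c(1, 0, 0)) {
  l <- drop(.check_unit_directions(l))
  t <- drop(.check_unit_directions(t))
  if (abs(sum(l * t)) > 1e-10) {
    .axdt_stop("axdt_invalid_argument",
               "grating orientation must be orthogonal to the beam")
  }
  structure(list(l = l, t = t, s = sensitivity_direction(l, t)),
            class = "grating_frame")
}

#' Grating frame as seen from the sample
#'
#' Rotating the sample by `R` with a fixed laboratory frame is equivalent to
#' keeping the sample fixed and rotating the frame by `R^T`. The forward
#' model works in this fixed-sample view.
#'
#' @param pose An [pose()].
#' @param frame A [grating_frame()].
#' @return A [grating_frame()] expressed in sample coordinates.
#' @export
effective_frame <- function(pose, frame) {
  Rt <- t(pose$rotation)
  structure(list(l = drop(Rt %*% frame$l),
                 t = drop(Rt %*% frame$t),
                 s = drop(Rt %*% frame$s)),
            class = "grating_frame")
}

#' Parallel-ray detector specification
#'
#' @param nu,nv Pixel counts along the detector u (grating `t`) and v
#'   (sensitivity `s`) axes.
#' @param pitch Pixel pitch in mm.
#' @return Object of class `detector_spec`.
#' @export
detector_spec <- function(nu, nv = nu, pitch = 1) {
  stopifnot(nu >= 1, nv >= 1, pitch > 0)
  structure(list(nu = as.integer(nu), nv = as.integer(nv),
                 pitch = as.numeric(pitch)),
            class = "detector_spec")
}

# Rotation taking unit vector `from` onto unit vector `to` (Rodrigues).
.rotation_between <- function(from, to) {
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  cth <- sum(from * to)
  if (sum(v^2) < 1e-24) {
    if (cth > 0) return(diag(3))
    # antipodal: rotate by pi about any axis orthogonal to `from`
    a <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a <- a - sum(a * from) * from
    a <- a / sqrt(sum(a^2))
    return(2 * outer(a, a) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

# Extrinsic Z-Y-Z angles (alpha, beta, gamma) with
# R = Rz(alpha) Ry(beta) Rz(gamma).
.euler_zyz <- function(R) {
  beta <- acos(pmin(1, pmax(-1, R[3, 3])))
  if (sin(beta) > 1e-12) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else {
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
  }
  c(alpha, beta, gamma)
}

# Incremental quasi-uniform hemisphere sequence: golden-angle azimuth with a
# van der Corput (base-2) z coordinate, so any prefix is low-discrepancy and
# pose sets at growing n are nested.
.hemisphere_sequence <- function(n, seed = 0) {
  vdc <- vapply(seq_len(n), function(j) {
    x <- 0; f <- 0.5
    while (j > 0) {
      x <- x + f * (j %% 2)
      j <- j %/% 2
      f <- f / 2
    }
    x
  }, numeric(1))
  phi0 <- 2 * pi * ((seed * 0.754877666) %% 1)
  phi <- phi0 + 2 * pi * (seq_len(n) * 0.618033988749895)
  z <- pmin(1 - 1e-9, pmax(1e-9, vdc))
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build an Euler-cradle acquisition protocol
#'
#' An anisotropic dark-field signal cannot be sampled completely from a
#' single tomographic axis; the sample must be rotated fully in 3D. Euler
#' poses are chosen so the effective sensitivity directions (the lab
#' sensitivity direction seen from the sample) are quasi-uniform on the
#' hemisphere, using an incremental golden-angle / van-der-Corput target
#' sequence: pose sets at growing `n_euler_poses` are nested, so coverage
#' can only improve. Each Euler pose is combined with `n_tomo_angles`
#' equispaced tomographic angles in `[0, pi)`; the tomographic axis
#' coincides with the sensitivity direction, so tomo rotation varies the ray
#' directions without changing the sampled scattering direction.
#'
#' @param n_euler_poses Number of distinct Euler-cradle orientations.
#' @param n_tomo_angles Number of tomographic angles per Euler orientation.
#' @param detector A [detector_spec()].
#' @param seed Integer; rotates the azimuth of the target sequence
#'   (deterministic given the seed).
#' @param frame Laboratory [grating_frame()].
#' @return Object of class `acquisition_protocol` with `poses` (list of
#'   [pose()]), `frame` and `detector`.
#' @export
build_protocol <- function(n_euler_poses, n_tomo_angles,
                           detector = detector_spec(16, 16, 1),
                           seed = 0, frame = grating_frame()) {
  stopifnot(n_euler_poses >= 1, n_tomo_angles >= 1)
  targets <- .hemisphere_sequence(n_euler_poses, seed)
  poses <- vector("list", n_euler_poses * n_tomo_angles)
  k <- 1L
  for (i in seq_len(n_euler_poses)) {
    # Euler rotation mapping the target direction onto the lab sensitivity
    # axis, so that R^T s equals the target.
    R <- .rotation_between(targets[i, ], frame$s)
    eul <- .euler_zyz(R)
    # Equispaced tomo angles, golden-angle staggered across Euler poses so
    # the view directions stay well spread even at small n_tomo_angles.
    tomo <- (seq_len(n_tomo_angles) - 1 + (i * 0.618033988749895) %% 1) *
      pi / n_tomo_angles
    for (j in seq_len(n_tomo_angles)) {
      poses[[k]] <- pose(eul, tomo[j])
      k <- k + 1L
    }
  }
  structure(list(poses = poses, frame = frame, detector = detector),
            class = "acquisition_protocol")
}

#' Effective sensitivity directions of a protocol
#'
#' @param protocol An [acquisition_protocol()].
#' @return n_pose x 3 matrix of unit vectors `R^T s`.
#' @export
protocol_sensitivities <- function(protocol) {
  t(vapply(protocol$poses,
           function(p) drop(t(p$rotation) %*% protocol$frame$s),
           numeric(3)))
}

#' Hemisphere coverage diagnostic of an acquisition protocol
#'
#' Optimal pose sampling for this modality is an open design problem; this
#' diagnostic reports the largest angular gap: the maximum, over a dense
#' hemisphere grid, of the angular distance to the nearest effective
#' sensitivity direction (antipodes identified). Smaller is better.
#'
#' @param protocol An [acquisition_protocol()], or an n x 3 matrix of
#'   directions.
#' @param grid_subdivisions Icosphere subdivision level of the test grid.
#' @return Worst-case angular gap in radians.
#' @export
protocol_coverage <- function(protocol, grid_subdivisions = 4) {
  dirs <- if (inherits(protocol, "acquisition_protocol")) {
    protocol_sensitivities(protocol)
  } else {
    rbind(protocol)
  }
  grid <- icosphere(grid_subdivisions, collapse_antipodes = TRUE)
  ip <- abs(grid$directions %*% t(dirs))  # antipodes identified
  max(acos(pmin(1, apply(ip, 1, max))))
}
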