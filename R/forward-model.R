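#' Voxelized spherical-scattering volume
#'
#' Holds one real even-degree spherical-harmonics coefficient vector per
#' voxel: the scattering profile eta(r, e) mapping scattering direction `e`
#' to scattering strength per mm at voxel `r`. World coordinates are
#' voxel-centered: the center of voxel `(i, j, k)` (0-based) sits at
#' `origin + (index + 0.5) * spacing`.
#'
#' @param coefficients 4D numeric array `(nx, ny, nz, K)`.
#' @param basis The shared [sh_basis()]; `K` must equal `basis$size`.
#' @param spacing Voxel spacing in mm (scalar, isotropic).
#' @param origin World coordinate (mm) of the grid corner; defaults to
#'   centering the volume on the world origin.
#' @return Object of class `scattering_volume`.
#' @export
scattering_volume <- function(coefficients, basis, spacing = 1,
                              origin = NULL) {
  stopifnot(inherits(basis, "sh_basis"), spacing > 0)
  dm <- dim(coefficients)
  if (length(dm) != 4L || dm[4] != basis$size) {
    .axdt_stop("axdt_invalid_argument",
               "coefficients must be (nx, ny, nz, K = %d)", basis$size)
  }
  if (is.null(origin)) origin <- -dm[1:3] * spacing / 2
  structure(list(coefficients = coefficients, basis = basis,
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 dims = as.integer(dm[1:3])),
            class = "scattering_volume")
}

#' Empty (all-zero) scattering volume
#' @param dims Length-3 integer grid shape.
#' @inheritParams scattering_volume
#' @return A [scattering_volume()] of zeros.
#' @export
zero_volume <- function(dims, basis, spacing = 1, origin = NULL) {
  scattering_volume(array(0, c(dims, basis$size)), basis, spacing, origin)
}

#' Dark-field sinogram
#'
#' Per-pose 2D detector arrays of dark-field values. In the transmission
#' domain values are the visibility reduction `d` in `(0, 1]`; in the log
#' domain they are `p = -log(d) >= 0`, the domain in which the tomographic
#' model is linear.
#'
#' @param data 3D array `(nu, nv, n_pose)`.
#' @param domain `"transmission"` (d) or `"log"` (p).
#' @return Object of class `darkfield_sinogram`.
#' @export
darkfield_sinogram <- function(data, domain = c("log", "transmission")) {
  domain <- match.arg(domain)
  stopifnot(length(dim(data)) == 3L)
  if (any(!is.finite(data))) {
    .axdt_stop("axdt_invalid_data", "sinogram contains non-finite values")
  }
  if (domain == "transmission" && (any(data <= 0) || any(data > 1))) {
    .axdt_stop("axdt_invalid_data",
               "transmission-domain dark-field values must lie in (0, 1]")
  }
  # log-domain arrays also carry solver residuals, so any finite real is
  # accepted here; the p >= 0 physical constraint is enforced on file I/O
  structure(list(data = data, domain = domain), class = "darkfield_sinogram")
}

#' Convert a sinogram to the log domain
#' @param sinogram A [darkfield_sinogram()].
#' @return A log-domain [darkfield_sinogram()] with `p = -log(d)`.
#' @export
sinogram_log <- function(sinogram) {
  stopifnot(inherits(sinogram, "darkfield_sinogram"))
  if (sinogram$domain == "log") return(sinogram)
  darkfield_sinogram(-log(sinogram$data), "log")
}

.funk_hecke_lambda_cos2 <- function(l) {
  # 2*pi * integral of t^2 P_l(t) dt over [-1, 1]
  ifelse(l == 0, 4 * pi / 3, ifelse(l == 2, 8 * pi / 15, 0))
}

#' Grating-sensitivity kernel weights
#'
#' Per unit path, a voxel with coefficients `c` contributes
#' `sum_k w_k c_k` to the log dark-field signal, with
#' `w_k = integral over the sphere of Y_k(e) h(e; s) de`. The default kernel
#' `h(e; s) = <e, s>^2` encodes that the grating picks up scattering along
#' the sensitivity direction `s` (orthogonal to the bars) and none along the
#' bars; by the Funk-Hecke theorem its weights are analytic and vanish for
#' degrees above 2, so only degrees {0, 2} are observable. The `"abs"`
#' kernel `h = |<e, s>|` is evaluated by high-order sphere quadrature and
#' retains degree-4 sensitivity.
#'
#' @param frame A [grating_frame()] (uses its sensitivity direction `s`).
#' @param basis An [sh_basis()].
#' @param kernel `"cos2"` (default) or `"abs"`.
#' @return Length-K numeric weight vector.
#' @export
kernel_weights <- function(frame, basis, kernel = "cos2") {
  stopifnot(inherits(frame, "grating_frame"), inherits(basis, "sh_basis"))
  s <- frame$s
  Ys <- drop(sh_design_matrix(basis, rbind(s)))
  if (identical(kernel, "cos2")) {
    lam <- .funk_hecke_lambda_cos2(basis$degrees$l)
    return(lam * Ys)
  }
  if (identical(kernel, "abs")) {
    # Funk-Hecke: w_k = lambda_l Y_k(s), lambda_l = 2 pi int_{-1}^{1} |t| P_l(t) dt.
    # |t| is polynomial on [0, 1], so Gauss-Legendre there is exact; even
    # degrees double the half-range integral.
    gl <- pracma::gaussLegendre(32, 0, 1)
    lam_of <- function(l) {
      Pl <- vapply(gl$x, function(t) pracma::legendre(l, t)[1], numeric(1))
      4 * pi * sum(gl$w * gl$x * Pl)
    }
    ls <- unique(basis$degrees$l)
    lam <- vapply(ls, lam_of, numeric(1))
    return(lam[match(basis$degrees$l, ls)] * Ys)
  }
  .axdt_stop("axdt_invalid_argument", "unknown kernel '%s'", kernel)
}

# Ray bundle of one pose in the fixed-sample view: point on each pixel ray
# plus the shared ray direction, both in sample/world coordinates.
.pose_rays <- function(pose, frame, detector, volume_center) {
  eff <- effective_frame(pose, frame)
  nu <- detector$nu; nv <- detector$nv; pitch <- detector$pitch
  du <- (seq_len(nu) - (nu + 1) / 2) * pitch
  dv <- (seq_len(nv) - (nv + 1) / 2) * pitch
  offsets_u <- outer(rep(du, times = nv), eff$t)
  offsets_v <- outer(rep(dv, each = nu), eff$s)
  p0 <- sweep(offsets_u + offsets_v, 2, volume_center, `+`)
  list(p0 = p0, dir = eff$l, eff = eff)
}

.volume_center <- function(volume) volume$origin + volume$dims * volume$spacing / 2

#' Line integral of a scalar voxel field along a ray
#'
#' Joseph-style interpolating line integral: the ray is traversed slice by
#' slice along its dominant axis with bilinear interpolation in the other
#' two, which is exact for axis-aligned rays through voxel centers. Rays
#' missing the volume integrate to 0.
#'
#' @param values 3D numeric array.
#' @param point A point on the ray (world mm).
#' @param direction Unit ray direction.
#' @param spacing Voxel spacing (mm).
#' @param origin World coordinate of the grid corner.
#' @return The mm-weighted line integral.
#' @export
ray_path_integral <- function(values, point, direction, spacing = 1,
                              origin = -dim(values) * spacing / 2) {
  direction <- drop(.check_unit_directions(direction))
  dm <- dim(values)
  stopifnot(length(dm) == 3L)
  out <- cpp_ray_integrals(as.numeric(values), c(dm, 1L),
                           rep(spacing, 3), origin,
                           rbind(point), direction)
  out[1, 1]
}

#' Forward-project a scattering volume to log-domain dark-field sinograms
#'
#' For each pose and detector pixel the model evaluates
#' `p = sum_k w_k(effective frame) * integral of c_k along the pixel ray`,
#' i.e. the grating-sensitivity contraction of Joseph line integrals of the
#' coefficient fields. Linear in the coefficients.
#'
#' @param volume A [scattering_volume()].
#' @param protocol An [acquisition_protocol()].
#' @param kernel Kernel name passed to [kernel_weights()].
#' @return A log-domain [darkfield_sinogram()].
#' @export
project <- function(volume, protocol, kernel = "cos2") {
  stopifnot(inherits(volume, "scattering_volume"),
            inherits(protocol, "acquisition_protocol"))
  det <- protocol$detector
  np <- length(protocol$poses)
  out <- array(0, c(det$nu, det$nv, np))
  ctr <- .volume_center(volume)
  dims4 <- c(volume$dims, volume$basis$size)
  # component-fastest layout for the compiled projector
  vol <- as.numeric(aperm(volume$coefficients, c(4, 1, 2, 3)))
  sp <- rep(volume$spacing, 3)
  for (ip in seq_len(np)) {
    rays <- .pose_rays(protocol$poses[[ip]], protocol$frame, det, ctr)
    w <- kernel_weights(rays$eff, volume$basis, kernel)
    ints <- cpp_ray_integrals(vol, dims4, sp, volume$origin, rays$p0, rays$dir)
    out[, , ip] <- matrix(ints %*% w, det$nu, det$nv)
  }
  darkfield_sinogram(out, "log")
}

#' Adjoint of the forward projector
#'
#' The exact transpose of [project()]: satisfies
#' `<project(x), y> = <x, backproject(y)>` for all volumes `x` and
#' log-domain sinograms `y`, as required by conjugate-gradient solvers.
#'
#' @param sinogram A log-domain [darkfield_sinogram()] (values may be any
#'   real numbers here: the adjoint is applied to residuals).
#' @param protocol An [acquisition_protocol()].
#' @param dims Length-3 grid shape.
#' @param basis An [sh_basis()].
#' @param spacing,origin Grid geometry as in [scattering_volume()].
#' @param kernel Kernel name passed to [kernel_weights()].
#' @return A [scattering_volume()].
#' @export
backproject <- function(sinogram, protocol, dims, basis, spacing = 1,
                        origin = NULL, kernel = "cos2") {
  stopifnot(inherits(sinogram, "darkfield_sinogram"),
            inherits(protocol, "acquisition_protocol"))
  det <- protocol$detector
  dsz <- dim(sinogram$data)
  if (dsz[1] != det$nu || dsz[2] != det$nv ||
      dsz[3] != length(protocol$poses)) {
    .axdt_stop("axdt_invalid_argument",
               "sinogram shape does not match protocol")
  }
  if (is.null(origin)) origin <- -dims * spacing / 2
  dims4 <- c(as.integer(dims), basis$size)
  acc <- numeric(prod(dims4))
  ctr <- origin + dims * spacing / 2
  sp <- rep(spacing, 3)
  for (ip in seq_along(protocol$poses)) {
    rays <- .pose_rays(protocol$poses[[ip]], protocol$frame, det, ctr)
    w <- kernel_weights(rays$eff, basis, kernel)
    cpp_backproject_rays(acc, dims4, sp, origin, rays$p0, rays$dir,
                         w, as.numeric(sinogram$data[, , ip]))
  }
  # accumulator is component-fastest; restore (nx, ny, nz, K)
  coefs <- aperm(array(acc, c(basis$size, dims)), c(2, 3, 4, 1))
  scattering_volume(coefs, basis, spacing, origin)
}

#' Simulate a noisy dark-field acquisition
#'
#' Computes the log-domain forward projection `p`, then
#' `d = exp(-p) * exp(sigma * xi)` with standard-normal `xi`
#' (multiplicative log-normal noise, the simplest noise model consistent
#' with positive visibility values), clipped to `(1e-12, 1]`. Deterministic
#' given `seed`.
#'
#' @inheritParams project
#' @param noise_sigma Log-domain noise standard deviation (>= 0).
#' @param seed Integer RNG seed.
#' @return A transmission-domain [darkfield_sinogram()].
#' @export
simulate_darkfield <- function(volume, protocol, noise_sigma = 0, seed = 1,
                               kernel = "cos2") {
  if (noise_sigma < 0) {
    .axdt_stop("axdt_invalid_argument", "noise_sigma must be >= 0")
  }
  p <- project(volume, protocol, kernel)$data
  d <- exp(-p)
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    d <- d * exp(noise_sigma * rnorm(length(d)))
  }
  d <- pmin(1, pmax(1e-12, d))
  darkfield_sinogram(array(d, dim(p)), "transmission")
}
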