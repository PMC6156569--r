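#' Real even-degree spherical-harmonics basis
#'
#' Dark-field scattering profiles are antipodally symmetric: a ray cannot
#' distinguish scattering direction `e` from `-e`. Odd spherical-harmonic
#' degrees are therefore unidentifiable and the basis is restricted to even
#' degrees. The basis is real-valued, orthonormal on the unit sphere and uses
#' no Condon-Shortley phase; coefficients are ordered by degree `l` ascending
#' (even only) and order `m = -l..l` ascending within each degree.
#'
#' @param max_degree Maximum spherical-harmonic degree `L`; must be even and
#'   non-negative.
#' @return An object of class `sh_basis` with fields `max_degree`, `degrees`
#'   (data frame of `(l, m)` pairs in canonical order) and `size` (number of
#'   basis functions `K`).
#' @examples
#' b <- sh_basis(4)
#' b$size  # 15
#' @export
sh_basis <- function(max_degree) {
  if (length(max_degree) != 1L || !is.finite(max_degree) ||
      max_degree < 0 || max_degree %% 2 != 0) {
    .axdt_stop("axdt_invalid_argument",
               "max_degree must be a non-negative even integer, got %s",
               format(max_degree))
  }
  L <- as.integer(max_degree)
  ls <- seq(0L, L, by = 2L)
  degrees <- do.call(rbind, lapply(ls, function(l) {
    data.frame(l = l, m = seq(-l, l))
  }))
  structure(list(max_degree = L, degrees = degrees, size = nrow(degrees)),
            class = "sh_basis")
}

#' Number of even-degree real spherical harmonics up to a maximum degree
#'
#' @param max_degree Even, non-negative maximum degree.
#' @return `sum_{l = 0, 2, ..., L} (2l + 1)`.
#' @export
sh_basis_size <- function(max_degree) {
  sh_basis(max_degree)$size
}

#' Spherical-harmonics coefficient vector
#'
#' Bundles a coefficient vector with its basis. Coefficients have units of
#' scattering strength per unit length (per mm).
#'
#' @param values Numeric vector of length `basis$size`.
#' @param basis An [sh_basis()].
#' @return An object of class `sh_coefficients`.
#' @export
sh_coefficients <- function(values, basis) {
  stopifnot(inherits(basis, "sh_basis"))
  values <- as.numeric(values)
  if (length(values) != basis$size) {
    .axdt_stop("axdt_invalid_argument",
               "coefficient length %d does not match basis size %d",
               length(values), basis$size)
  }
  if (!all(is.finite(values))) {
    .axdt_stop("axdt_invalid_argument", "coefficients must be finite")
  }
  structure(list(values = values, basis = basis), class = "sh_coefficients")
}

.check_unit_directions <- function(directions, tol = 1e-6) {
  directions <- rbind(directions)
  if (ncol(directions) != 3L) {
    .axdt_stop("axdt_invalid_argument", "directions must be n x 3")
  }
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > tol)) {
    .axdt_stop("axdt_invalid_argument",
               "directions must be unit-norm (max deviation %.2e)",
               max(abs(nrm - 1)))
  }
  directions
}

#' Design matrix of real spherical harmonics at a set of directions
#'
#' Row `i`, column `k` holds `Y_k(direction_i)` in the canonical even-degree
#' ordering of [sh_basis()]. Associated Legendre values come from
#' [pracma::legendre()] (MATLAB convention); the Condon-Shortley phase is
#' removed so that the basis sign convention is phase-free.
#'
#' @param basis An [sh_basis()].
#' @param directions n x 3 matrix of unit vectors.
#' @return n x K numeric matrix.
#' @export
sh_design_matrix <- function(basis, directions) {
  stopifnot(inherits(basis, "sh_basis"))
  directions <- .check_unit_directions(directions)
  n <- nrow(directions)
  ct <- pmin(1, pmax(-1, directions[, 3]))
  phi <- atan2(directions[, 2], directions[, 1])
  out <- matrix(0, n, basis$size)
  col <- 1L
  for (l in seq(0L, basis$max_degree, by = 2L)) {
    # rows m = 0..l; pracma uses the Condon-Shortley (-1)^m convention
    P <- pracma::legendre(l, ct)
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1L)
    for (m in seq(-l, l)) {
      am <- abs(m)
      # orthonormalization constant
      Klm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      plm <- (-1)^am * P[am + 1L, ]  # strip Condon-Shortley phase
      out[, col] <- if (m == 0) {
        Klm * plm
      } else if (m > 0) {
        sqrt(2) * Klm * plm * cos(m * phi)
      } else {
        sqrt(2) * Klm * plm * sin(am * phi)
      }
      col <- col + 1L
    }
  }
  out
}

#' Evaluate a spherical-harmonics expansion at directions on the sphere
#'
#' @param coeffs An [sh_coefficients()].
#' @param directions n x 3 matrix (or length-3 vector) of unit directions.
#' @return Numeric vector of function values, one per direction.
#' @export
evaluate_sh <- function(coeffs, directions) {
  stopifnot(inherits(coeffs, "sh_coefficients"))
  B <- sh_design_matrix(coeffs$basis, directions)
  drop(B %*% coeffs$values)
}

#' Least-squares fit of spherical-harmonics coefficients to sphere samples
#'
#' Solves `min_c ||B c - v||^2 + lambda * sum_k (l_k (l_k + 1))^2 c_k^2`,
#' the optional penalty being the squared Laplace-Beltrami operator weight.
#' With `regularization_weight = 0` the system must be overdetermined and of
#' full column rank.
#'
#' @param directions n x 3 unit directions of the samples.
#' @param values Numeric vector of sampled function values.
#' @param basis An [sh_basis()].
#' @param regularization_weight Non-negative Laplace-Beltrami penalty weight.
#' @return An [sh_coefficients()].
#' @export
fit_sh <- function(directions, values, basis, regularization_weight = 0) {
  stopifnot(inherits(basis, "sh_basis"), regularization_weight >= 0)
  directions <- .check_unit_directions(directions)
  if (length(values) != nrow(directions)) {
    .axdt_stop("axdt_invalid_argument",
               "values length must match number of directions")
  }
  B <- sh_design_matrix(basis, directions)
  if (regularization_weight == 0) {
    if (nrow(B) < ncol(B)) {
      .axdt_stop("axdt_rank_deficient",
                 "underdetermined fit: %d samples < %d coefficients",
                 nrow(B), ncol(B))
    }
    qrB <- qr(B)
    if (qrB$rank < ncol(B)) {
      .axdt_stop("axdt_rank_deficient",
                 "rank-deficient design matrix (rank %d < %d)",
                 qrB$rank, ncol(B))
    }
    c_hat <- qr.coef(qrB, values)
  } else {
    lb <- basis$degrees$l * (basis$degrees$l + 1)
    Baug <- rbind(B, sqrt(regularization_weight) * diag(lb, basis$size))
    vaug <- c(values, numeric(basis$size))
    c_hat <- qr.coef(qr(Baug), vaug)
  }
  sh_coefficients(c_hat, basis)
}

#' Legendre polynomial at zero
#'
#' `P_l(0)` is 0 for odd `l` and `(-1)^(l/2) (l-1)!! / l!!` for even `l`;
#' these are the per-degree eigenvalue factors of the Funk-Radon transform.
#'
#' @param l Non-negative integer degree (vectorized).
#' @return `P_l(0)`.
#' @export
legendre_at_zero <- function(l) {
  if (any(l < 0) || any(l != round(l))) {
    .axdt_stop("axdt_invalid_argument", "l must be a non-negative integer")
  }
  vapply(as.integer(l), function(li) {
    if (li %% 2 == 1) return(0)
    if (li == 0) return(1)
    k <- seq(2, li, by = 2)
    (-1)^(li / 2) * prod((k - 1) / k)
  }, numeric(1))
}

#' Funk-Radon transform in spherical-harmonics coefficient space
#'
#' The Funk-Radon transform maps a spherical function to its great-circle
#' integrals: the value at direction `u` is the integral of the function over
#' the great circle orthogonal to `u`. In the spherical-harmonics basis the
#' transform is diagonal, scaling every degree-`l` coefficient by
#' `2 * pi * P_l(0)`. For girdle-shaped (plate-like) scattering profiles this
#' converts the girdle plane into a peak along the fiber axis.
#'
#' @param coeffs An [sh_coefficients()].
#' @return An [sh_coefficients()] holding the transformed expansion.
#' @export
funk_radon_sh <- function(coeffs) {
  stopifnot(inherits(coeffs, "sh_coefficients"))
  scale <- funk_radon_eigenvalues(coeffs$basis)
  sh_coefficients(coeffs$values * scale, coeffs$basis)
}

#' Per-coefficient Funk-Radon eigenvalues for a basis
#'
#' @param basis An [sh_basis()].
#' @return Length-K vector `2 * pi * P_l(0)` following the basis ordering.
#' @export
funk_radon_eigenvalues <- function(basis) {
  stopifnot(inherits(basis, "sh_basis"))
  2 * pi * legendre_at_zero(basis$degrees$l)
}

#' Brute-force Funk-Radon transform by great-circle quadrature
#'
#' Trapezoidal integration of [evaluate_sh()] over the great circle orthogonal
#' to `direction`, using `n_quadrature` equispaced points (periodic, so the
#' trapezoidal rule reduces to the mean times the circumference `2 * pi`).
#' Exists as an independent check of the analytic [funk_radon_sh()].
#'
#' @param coeffs An [sh_coefficients()].
#' @param direction Unit 3-vector.
#' @param n_quadrature Number of quadrature points (>= 8).
#' @return The great-circle integral (scalar).
#' @export
funk_radon_numeric <- function(coeffs, direction, n_quadrature = 256) {
  stopifnot(n_quadrature >= 8)
  direction <- drop(.check_unit_directions(direction))
  e1 <- if (abs(direction[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * direction) * direction
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(direction[2] * e1[3] - direction[3] * e1[2],
          direction[3] * e1[1] - direction[1] * e1[3],
          direction[1] * e1[2] - direction[2] * e1[1])
  t <- 2 * pi * (seq_len(n_quadrature) - 1) / n_quadrature
  pts <- outer(cos(t), e1) + outer(sin(t), e2)
  2 * pi * mean(evaluate_sh(coeffs, pts))
}

#' Product quadrature rule on the unit sphere
#'
#' Gauss-Legendre nodes in `cos(theta)` crossed with equispaced azimuths;
#' integrates spherical polynomials up to degree `2 * n_theta - 1` exactly.
#' Used for orthonormality checks and numeric kernel weights.
#'
#' @param n_theta Number of Gauss-Legendre polar nodes.
#' @param n_phi Number of azimuthal nodes (defaults to `2 * n_theta`).
#' @return List with `directions` (n x 3) and `weights` (summing to `4 * pi`).
#' @export
sphere_quadrature <- function(n_theta = 12, n_phi = 2 * n_theta) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  ct <- rep(gl$x, each = n_phi)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phi, times = n_theta)
  directions <- cbind(st * cos(ph), st * sin(ph), ct)
  weights <- rep(gl$w, each = n_phi) * (2 * pi / n_phi)
  list(directions = directions, weights = weights)
}
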