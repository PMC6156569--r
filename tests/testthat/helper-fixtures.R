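# Shared helpers for the test suite. All fixtures are generated in code.

random_unit_vectors <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

random_volume <- function(dims, basis, seed = 1, spacing = 1) {
  set.seed(seed)
  scattering_volume(array(rnorm(prod(dims) * basis$size),
                          c(dims, basis$size)),
                    basis, spacing)
}

rel_err <- function(est, truth) {
  sqrt(sum((est - truth)^2)) / sqrt(sum(truth^2))
}

angle_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
}

# protocol with the same total rotations but an extra sample rotation R
# applied first (used by the rotational-equivariance check)
rotate_protocol <- function(protocol, R) {
  poses <- lapply(protocol$poses, function(p) {
    axdt:::pose(axdt:::.euler_zyz(p$rotation %*% t(R)), 0)
  })
  structure(list(poses = poses, frame = protocol$frame,
                 detector = protocol$detector),
            class = "acquisition_protocol")
}

# orientation field filled from phantom ground truth (isolates tractography
# from reconstruction error)
truth_orientation_field <- function(phantom) {
  vol <- phantom$volume
  nvox <- prod(vol$dims)
  principal <- matrix(NA_real_, nvox, 3)
  magnitude <- rep(NA_real_, nvox)
  for (v in seq_len(nvox)) {
    td <- phantom$directions[[v]]
    if (!is.null(td)) {
      principal[v, ] <- td[1, ]
      magnitude[v] <- 1
    }
  }
  structure(list(principal = principal, magnitude = magnitude,
                 anisotropy = rep(1, nvox), peaks = vector("list", nvox),
                 dims = vol$dims, spacing = vol$spacing, origin = vol$origin,
                 thresholds = list()),
            class = "orientation_field")
}
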