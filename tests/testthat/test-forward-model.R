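test_that("squared-cosine kernel weights follow the Funk-Hecke closed form", {
  basis <- sh_basis(4)
  w <- kernel_weights(grating_frame(), basis)
  expect_equal(w[1], sqrt(4 * pi) / 3, tolerance = 1e-12)
  # the kernel is a degree-2 polynomial: degree-4 weights vanish
  expect_equal(w[basis$degrees$l == 4], rep(0, 9))
  # degree-0 weight is rotation invariant
  set.seed(31)
  w0 <- vapply(1:20, function(i) {
    p <- pose(runif(3, -pi, pi), runif(1, 0, pi))
    kernel_weights(effective_frame(p, grating_frame()), basis)[1]
  }, numeric(1))
  expect_lt(diff(range(w0)), 1e-12)
  expect_error(kernel_weights(grating_frame(), basis, "sinc"),
               class = "axdt_invalid_argument")
})

test_that("absolute-value kernel weights match a 1D Funk-Hecke oracle", {
  basis <- sh_basis(4)
  frame <- grating_frame()
  w <- kernel_weights(frame, basis, "abs")
  # Funk-Hecke: w_k = lambda_l * Y_k(s), lambda_l = 2 pi int |t| P_l(t) dt
  lam <- vapply(c(0, 2, 4), function(l) {
    2 * pi * stats::integrate(function(t) {
      abs(t) * vapply(t, function(ti) pracma::legendre(l, ti)[1], numeric(1))
    }, -1, 1, rel.tol = 1e-12)$value
  }, numeric(1))
  Ys <- drop(sh_design_matrix(basis, rbind(frame$s)))
  expected <- lam[match(basis$degrees$l, c(0, 2, 4))] * Ys
  expect_equal(w, expected, tolerance = 1e-8)
  # degree-4 stays observable under this kernel
  expect_gt(max(abs(w[basis$degrees$l == 4])), 1e-3)
})

test_that("Joseph line integrals are exact on axis-aligned rays", {
  vol <- array(1, c(8, 8, 8))
  # ray along +x through the center of voxel row (y = z = 3rd index)
  p0 <- c(-100, -4 + 2.5, -4 + 2.5)
  expect_equal(ray_path_integral(vol, p0, c(1, 0, 0), spacing = 1), 8)
  expect_equal(ray_path_integral(array(0, c(8, 8, 8)), p0, c(1, 0, 0)), 0)
  # ray missing the volume
  expect_equal(ray_path_integral(vol, c(0, 50, 0), c(1, 0, 0)), 0)
})

test_that("Joseph integrals match dense ray sampling on oblique rays", {
  # smooth random field: both quadratures converge to the same integral
  # (on voxel-scale noise they would differ at the interpolation scale)
  set.seed(41)
  a <- rnorm(6)
  g <- seq_len(16)
  taper <- sin(pmin(1, pmin(g - 1, 16 - g) / 4) * pi / 2)^2
  vol <- array(0, c(16, 16, 16))
  for (i in g) for (j in g) for (k in g) {
    vol[i, j, k] <- (2 + a[1] * sin(i / 4) + a[2] * cos(j / 5) +
      a[3] * sin(k / 6) + a[4] * sin((i + j) / 7) + a[5] * cos((j + k) / 8) +
      a[6] * sin((i + k) / 9)) * taper[i] * taper[j] * taper[k]
  }
  d <- c(1, 1, 0) / sqrt(2)
  p0 <- c(0, 0, 0.3)
  joseph <- ray_path_integral(vol, p0, d, spacing = 1)
  # brute-force oracle: 10k-point midpoint rule with trilinear interpolation
  tt <- seq(-16, 16, length.out = 10000)
  step <- tt[2] - tt[1]
  interp <- function(q) {
    f <- (q - (-8)) / 1 - 0.5
    i0 <- floor(f); w1 <- f - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ijk <- i0 + c(dx, dy, dz)
      if (any(ijk < 0) || any(ijk > 15)) next
      w <- prod(ifelse(c(dx, dy, dz) == 1, w1, 1 - w1))
      acc <- acc + w * vol[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1]
    }
    acc
  }
  dense <- sum(vapply(tt, function(s) interp(p0 + s * d), numeric(1))) * step
  expect_lt(abs(joseph - dense) / abs(dense), 1e-2)
})

test_that("projection is linear and vanishes on the zero volume", {
  basis <- sh_basis(2)
  prot <- build_protocol(4, 2, detector_spec(10, 10, 1), seed = 1)
  z <- zero_volume(c(6, 6, 6), basis)
  expect_equal(max(abs(project(z, prot)$data)), 0)
  x <- random_volume(c(6, 6, 6), basis, seed = 42)
  y <- random_volume(c(6, 6, 6), basis, seed = 43)
  ax <- project(x, prot)$data
  ay <- project(y, prot)$data
  xy <- scattering_volume(2 * x$coefficients - 3 * y$coefficients, basis, 1)
  expect_equal(project(xy, prot)$data, 2 * ax - 3 * ay, tolerance = 1e-12)
})

test_that("isotropic voxel fields project to kernel weight times path length", {
  basis <- sh_basis(2)
  n <- 8
  coef <- array(0, c(n, n, n, 6))
  coef[, , , 1] <- 2.0
  vol <- scattering_volume(coef, basis, spacing = 1)
  # axis-aligned pose: beam along z, odd detector gives a central ray
  prot <- structure(list(poses = list(pose(c(0, 0, 0), 0)),
                         frame = grating_frame(),
                         detector = detector_spec(9, 9, 1)),
                    class = "acquisition_protocol")
  p <- project(vol, prot)$data
  expect_equal(p[5, 5, 1], (sqrt(4 * pi) / 3) * 2.0 * n, tolerance = 1e-10)
})

test_that("backprojection is the exact adjoint of projection", {
  basis <- sh_basis(2)
  prot <- build_protocol(10, 1, detector_spec(12, 12, 0.8), seed = 2)
  x <- random_volume(c(8, 8, 8), basis, seed = 51, spacing = 1)
  set.seed(52)
  y <- array(rnorm(12 * 12 * 10), c(12, 12, 10))
  ax <- project(x, prot)$data
  aty <- backproject(darkfield_sinogram(y, "log"), prot, c(8, 8, 8), basis,
                     spacing = 1)$coefficients
  lhs <- sum(ax * y)
  rhs <- sum(x$coefficients * aty)
  expect_lt(abs(lhs - rhs) / (sqrt(sum(ax^2)) * sqrt(sum(y^2))), 1e-10)
})

test_that("backprojecting a single-ray impulse only touches traversed voxels", {
  basis <- sh_basis(0)
  prot <- structure(list(poses = list(pose(c(0, 0, 0), 0)),
                         frame = grating_frame(),
                         detector = detector_spec(9, 9, 1)),
                    class = "acquisition_protocol")
  y <- array(0, c(9, 9, 1))
  y[5, 5, 1] <- 1  # central ray, beam along z
  bp <- backproject(darkfield_sinogram(y, "log"), prot, c(8, 8, 8), basis,
                    spacing = 1)$coefficients[, , , 1]
  touched <- which(bp != 0, arr.ind = TRUE)
  # central ray at x = y = 0 interpolates between the two middle columns
  expect_true(all(touched[, 1] %in% c(4, 5)))
  expect_true(all(touched[, 2] %in% c(4, 5)))
  z <- backproject(darkfield_sinogram(array(0, c(9, 9, 1)), "log"), prot,
                   c(8, 8, 8), basis)
  expect_equal(max(abs(z$coefficients)), 0)
})

test_that("dark-field simulation is seeded, clipped and log-consistent", {
  basis <- sh_basis(2)
  prot <- build_protocol(5, 1, detector_spec(8, 8, 1), seed = 1)
  z <- zero_volume(c(6, 6, 6), basis)
  expect_equal(unique(as.vector(simulate_darkfield(z, prot)$data)), 1)

  fx <- make_fixture("straight", 8, seed = 1)
  p <- project(fx$volume, fx$protocol)$data
  d0 <- simulate_darkfield(fx$volume, fx$protocol, 0, seed = 1)
  expect_equal(-log(d0$data), p, tolerance = 1e-12)

  d1 <- simulate_darkfield(fx$volume, fx$protocol, 0.01, seed = 7)
  d2 <- simulate_darkfield(fx$volume, fx$protocol, 0.01, seed = 7)
  expect_identical(d1$data, d2$data)
  expect_true(all(d1$data > 0 & d1$data <= 1))
  expect_error(simulate_darkfield(fx$volume, fx$protocol, -0.1),
               class = "axdt_invalid_argument")
})

test_that("log dark-field peaks when the sensitivity is orthogonal to the fiber", {
  # single-fiber voxel block, fiber along z; sweep s from parallel (theta=0)
  # to orthogonal (theta=90 deg) with the beam fixed along y
  basis <- sh_basis(2)
  prof <- girdle_profile_sh(c(0, 0, 1), strength = 0.2, kappa = 5, basis)
  n <- 5
  coef <- array(0, c(n, n, n, 6))
  for (k in 1:6) coef[3, 3, 3, k] <- prof$values[k]
  vol <- scattering_volume(coef, basis, spacing = 1)
  l <- c(0, 1, 0)
  theta <- seq(0, pi / 2, length.out = 10)
  p_central <- vapply(theta, function(th) {
    s <- cos(th) * c(0, 0, 1) + sin(th) * c(1, 0, 0)
    t_dir <- c(s[2] * l[3] - s[3] * l[2], s[3] * l[1] - s[1] * l[3],
               s[1] * l[2] - s[2] * l[1])
    prot <- structure(list(poses = list(pose(c(0, 0, 0), 0)),
                           frame = grating_frame(l, t_dir),
                           detector = detector_spec(5, 5, 1)),
                      class = "acquisition_protocol")
    project(vol, prot)$data[3, 3, 1]
  }, numeric(1))
  expect_true(all(diff(p_central) > 0))              # monotone over the sweep
  expect_equal(which.min(p_central), 1)              # minimal at s parallel f
  expect_equal(which.max(p_central), length(theta))  # maximal at s orthogonal
})
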