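test_that("voxelwise Funk-Radon matches the per-voxel transform", {
  basis <- sh_basis(4)
  vol <- random_volume(c(4, 4, 4), basis, seed = 61)
  frt <- funk_radon_volume(vol)
  cmat <- matrix(vol$coefficients, 64, basis$size)
  fmat <- matrix(frt$coefficients, 64, basis$size)
  set.seed(62)
  for (v in sample(64, 20)) {
    expect_equal(fmat[v, ],
                 funk_radon_sh(sh_coefficients(cmat[v, ], basis))$values,
                 tolerance = 1e-14)
  }
  z <- zero_volume(c(3, 3, 3), basis)
  expect_equal(max(abs(funk_radon_volume(z)$coefficients)), 0)
  iso <- zero_volume(c(3, 3, 3), basis)
  iso$coefficients[, , , 1] <- 1.5
  expect_equal(funk_radon_volume(iso)$coefficients[, , , 1],
               array(2 * pi * 1.5, c(3, 3, 3)), tolerance = 1e-14)
})

test_that("a girdle profile yields one Funk-Radon peak along the fiber", {
  basis <- sh_basis(4)
  f <- c(0, 0, 1)
  prof <- girdle_profile_sh(f, 1, kappa = 5, basis)
  frt <- funk_radon_sh(prof)
  grid <- icosphere(5, collapse_antipodes = TRUE)
  peaks <- extract_peaks(frt, grid)
  expect_equal(nrow(peaks$directions), 1)
  expect_lt(angle_deg(peaks$directions[1, ], f), 2)
  # magnitude agrees with the great-circle quadrature oracle
  expect_equal(peaks$magnitudes[1],
               funk_radon_numeric(prof, peaks$directions[1, ], 512),
               tolerance = 1e-3 * abs(peaks$magnitudes[1]))
})

test_that("isotropic profiles yield no peaks (flat-profile guard)", {
  basis <- sh_basis(4)
  iso <- numeric(basis$size); iso[1] <- 3
  grid <- icosphere(4, collapse_antipodes = TRUE)
  peaks <- extract_peaks(funk_radon_sh(sh_coefficients(iso, basis)), grid)
  expect_equal(nrow(peaks$directions), 0)
  expect_error(extract_peaks(sh_coefficients(iso, basis),
                             structure(list(directions = matrix(numeric(0), 0, 3),
                                            neighbors = list(),
                                            hemisphere = TRUE),
                                       class = "sphere_grid")),
               class = "axdt_invalid_argument")
})

test_that("crossing girdles produce two nearly orthogonal peaks", {
  basis <- sh_basis(4)
  two <- girdle_profile_sh(c(1, 0, 0), 1, 5, basis)$values +
    girdle_profile_sh(c(0, 1, 0), 1, 5, basis)$values
  frt <- funk_radon_sh(sh_coefficients(two, basis))
  grid <- icosphere(5, collapse_antipodes = TRUE)
  peaks <- extract_peaks(frt, grid, relative_threshold = 0.5)
  expect_equal(nrow(peaks$directions), 2)
  sep <- acos(min(1, abs(sum(peaks$directions[1, ] *
                               peaks$directions[2, ])))) * 180 / pi
  expect_gt(sep, 85)
})

test_that("anisotropy index separates girdles from isotropic profiles", {
  basis <- sh_basis(4)
  iso <- numeric(basis$size); iso[1] <- 2
  expect_equal(anisotropy_index(sh_coefficients(iso, basis)), 0)
  expect_equal(anisotropy_index(numeric(basis$size), basis), 0)
  a1 <- anisotropy_index(girdle_profile_sh(c(0, 0, 1), 1, 1, basis))
  a5 <- anisotropy_index(girdle_profile_sh(c(0, 0, 1), 1, 5, basis))
  expect_gt(a5, a1)
  expect_true(a5 >= 0 && a5 <= 1)
})

test_that("principal orientation field masks background and matches truth", {
  fx <- make_fixture("straight", 12, seed = 71)
  frt <- funk_radon_volume(fx$volume)   # ground-truth coefficients
  field <- principal_orientation_field(frt, icosphere(4, TRUE),
                                       magnitude_threshold = 0,
                                       anisotropy_threshold = 0.02)
  mask <- as.logical(fx$truth$mask)
  # background voxels carry no orientations
  bg <- which(!mask)
  expect_true(all(vapply(bg, function(v) {
    nrow(field$peaks[[v]]$directions) == 0
  }, logical(1))))
  err <- orientation_error(field, fx$truth)
  expect_gte(mean(err$errors_deg <= 5), 0.95)
})

test_that("streamlines advect straight through a uniform field", {
  # uniform +x orientations inside a 20-voxel-long slab
  dims <- c(24, 5, 5)
  nvox <- prod(dims)
  principal <- matrix(NA_real_, nvox, 3)
  magnitude <- rep(NA_real_, nvox)
  inmask <- function(i) i >= 3 && i <= 22
  for (i in 1:24) for (j in 1:5) for (k in 1:5) {
    v <- i + 24 * ((j - 1) + 5 * (k - 1))
    if (inmask(i)) { principal[v, ] <- c(1, 0, 0); magnitude[v] <- 1 }
  }
  field <- structure(list(principal = principal, magnitude = magnitude,
                          anisotropy = rep(1, nvox), peaks = list(),
                          dims = dims, spacing = 1, origin = -dims / 2,
                          thresholds = list()),
                     class = "orientation_field")
  sl <- track_streamlines(field, rbind(c(0.5, 0, 0)), step_mm = 0.5,
                          min_magnitude = 0.25)[[1]]
  span <- diff(range(sl$points[, 1]))
  expect_gte(span, 20 - 1 - 0.5)   # mask extent minus edge interpolation
  expect_lte(span, 20 + 0.5)
  # step size contract
  steps <- sqrt(rowSums(diff(sl$points)^2))
  expect_lt(max(abs(steps - 0.5)), 1e-9)

  # seed in an empty region: 2-point streamline, low magnitude
  sl0 <- track_streamlines(field, rbind(c(-11, 0, 0)), step_mm = 0.5)[[1]]
  expect_equal(nrow(sl0$points), 2)
  expect_match(sl0$reason, "low-magnitude")
  expect_error(track_streamlines(field, rbind(c(100, 0, 0))),
               class = "axdt_invalid_argument")
})

test_that("tracking is invariant under per-voxel sign flips", {
  fx <- make_fixture("straight", 12, seed = 72)
  field <- truth_orientation_field(fx$phantom)
  set.seed(73)
  flipped <- field
  flip <- runif(nrow(field$principal)) < 0.5
  flipped$principal[flip, ] <- -flipped$principal[flip, ]
  seeds <- rbind(c(0, 0, 0), c(1.1, 0.4, -0.3))
  a <- track_streamlines(field, seeds, step_mm = 0.25)
  b <- track_streamlines(flipped, seeds, step_mm = 0.25)
  for (i in seq_along(a)) {
    expect_equal(dim(a[[i]]$points), dim(b[[i]]$points))
    expect_lt(max(abs(a[[i]]$points - b[[i]]$points)), 1e-9)
  }
})
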