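---
title: "Anisotropic dark-field tomography: model, reconstruction and fiber extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anisotropic dark-field tomography: model, reconstruction and fiber extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axdt)
```

## The measurement physics being modeled

A Talbot–Lau grating interferometer records, besides attenuation and phase,
a *dark-field* channel: the reduction of interference-fringe visibility
caused by (ultra-)small-angle scattering inside the specimen, one value
`d in (0, 1]` per detector pixel. For specimens with aligned micrometer-scale
structure — the axon bundles of white matter are the canonical example —
this scattering is strongly anisotropic: a thin fiber scatters
predominantly into the plane orthogonal to its axis ("plate-like" or girdle
scattering). The interferometer only senses the scattering component along
its *sensitivity direction* `s`, the in-detector-plane unit vector
orthogonal to the grating bars `t` and the beam `l`
(`s = l x t`; `{t, s, l}` right-handed). The signal is therefore strongest
when the bars align with the fiber, i.e. when `s` is orthogonal to it.

Because one tomographic axis cannot sweep `s` over the sphere, the specimen
is mounted on an Euler cradle and rotated fully in 3D. `axdt` models this
acquisition, reconstructs the per-voxel scattering profile, and extracts
fiber orientations from it.

## Model

**Scattering profiles.** Each voxel `r` carries a spherical function
`eta(r, e)` (scattering strength per mm as a function of scattering
direction `e`), expanded in real orthonormal spherical harmonics. Only
*even* degrees are kept: a ray cannot distinguish `e` from `-e`, so odd
degrees are unidentifiable in principle and excluded by construction. The
sign convention is Condon–Shortley-free and the ordering is `(l, m)`
lexicographic with `m = -l..l`; both are recorded in every file sidecar so
coefficient volumes are portable.

**Forward model.** In the log domain `p = -log d` the model is linear. For
pose rotation `R` the fixed-sample view uses the effective frame
`(R^T l, R^T t, R^T s)`; a pixel's signal is

```
p = sum_k w_k(R^T s) * J_k,    w_k(s) = \int_{S^2} Y_k(e) h(e; s) de,
```

where `J_k` is the Joseph line integral of the k-th coefficient field along
the pixel ray and `h` is the grating-sensitivity kernel. The default kernel
is `h(e; s) = <e, s>^2`, the standard squared-cosine sensitivity model; its
weights have a Funk–Hecke closed form and vanish for degrees above 2, so
the default reconstruction degree is `L = 2` — higher degrees are simply
not observable and the solver provably leaves them at zero. An `"abs"`
kernel (`h = |<e, s>|`, weights by high-order product quadrature) is
provided for experiments that need degree-4 sensitivity. The kernel in
force is logged in all output metadata, since the physically correct
weighting for a given bench is itself a modeling choice.

**Geometry.** Parallel-beam rays, a fixed laboratory frame
(`l = (0,0,1)`, `t = (1,0,0)`, `s = (0,1,0)`, matching a bench where the
gratings do not move), extrinsic Z–Y–Z Euler angles for the cradle and a
tomographic rotation about the laboratory vertical axis (which coincides
with `s`, so tomographic rotation varies ray directions without changing
the sampled scattering direction). The equivalence of rotating the sample
and counter-rotating the frame is itself a test. Divergent-beam geometry is
out of scope; parallel rays keep the projector verifiable against analytic
path lengths.

**Protocol design.** Optimal pose sampling for this modality is an open
problem, so the package treats the protocol as data and provides one
reasonable generator plus a diagnostic. `build_protocol(n_euler, n_tomo)`
picks Euler targets from an incremental golden-angle/van-der-Corput
hemisphere sequence — prefixes of one fixed sequence, so pose sets are
nested and the coverage diagnostic (worst angular gap between effective
sensitivity directions, antipodes identified) is non-increasing in
`n_euler` by construction. Tomographic angles are equispaced in `[0, pi)`
and golden-angle-staggered across Euler poses so that even one tomo angle
per pose yields well-spread view directions; without the stagger, recovery
degrades noticeably because all poses share a single view per sensitivity
direction. The default study protocol is 80 Euler poses x 1 tomo angle:
coverage 0.345 rad and accurate recovery at 32^3.

## Reconstruction

CGLS on `min_x ||A x - p||^2 + lambda ||x||^2` with zero initialization,
a fixed iteration budget (stop early when the relative residual changes by
less than 1e-8), and Tikhonov regularization via the augmented operator.
The projector and its hand-written transpose agree to ~1e-12 relative (an
acceptance property), so the CGLS residual is monotone by construction; a
growth of more than 10x over the best residual raises a solver-failure
error. No nonnegativity constraint is imposed on the spherical functions —
instead `negativity_report()` counts voxels whose reconstructed profile
dips below zero, and the pipeline logs it. Degree-4 blocks reconstructed
under the default kernel are asserted to stay exactly zero.

## Fiber extraction

The Funk–Radon transform maps a spherical function to its great-circle
integrals; it is diagonal in the SH basis with eigenvalues `2*pi*P_l(0)`
(`P_0(0) = 1`, `P_2(0) = -1/2`, `P_4(0) = 3/8`). Girdle scattering
concentrated orthogonal to a fiber is thereby converted into a peak *along*
the fiber. A brute-force great-circle quadrature implementation exists
purely as an independent oracle for tests.

Peaks are local maxima on an icosphere grid (subdivision 4 by default:
2562 vertices, 1281 after antipodal collapse, ~4 degree resolution),
filtered by a relative threshold (default 0.5 of the per-voxel maximum) and
greedy angular suppression (default 15 degrees). A flat-profile guard
(max - min < 1e-6 of the max) reports no peaks for isotropic voxels, where
any grid argmax would be numerical noise. Directions are reported as
canonical antipodal representatives (positive z, ties broken by y then x).

Masking stands in for the anatomical fact that strongly scattering,
strongly oriented voxels are the fiber-bearing ones: voxels pass if their
peak Funk–Radon magnitude exceeds a threshold (by default the 0.7 quantile
of in-volume maxima — the white-matter-style mask; an absolute threshold
can be supplied instead) and their anisotropy index (degree >= 2 coefficient
energy over total) exceeds 0.05. The isotropic-baseline subtraction before
peak search is deliberately *not* performed by default; since degree 0 only
shifts all great-circle integrals by a constant, it does not move peak
locations, only the relative threshold's meaning.

Tractography is deterministic bidirectional Euler integration of the
principal-orientation field (step 0.5 voxel, max turning 60 degrees per
step, magnitude floor). Orientations are sign-ambiguous, so every
interpolated corner vector is sign-aligned with the incoming direction
before trilinear averaging; flipping signs voxel-wise provably leaves
tracked point sets unchanged. Crossing-fiber voxels report multiple peaks,
but tracking follows the principal peak only.

## Synthetic specimens

The generator emulates the study conditions of a bench-top dark-field scan
of a fibrous specimen at 0.5 mm effective voxels. Fiber primitives
(straight bundles, helices with analytic tangents, crossing pairs,
isotropic balls) assign each covered voxel a Watson-type girdle profile
`strength * N(kappa) * exp(-kappa <e, f>^2)` along the local tangent
(`N(kappa)` normalizes the spherical mean to 1), fitted to the band-limited
basis on a subdivision-4 icosphere. Defaults chosen once:

* `kappa = 5`: a clear girdle without exceeding what a degree-2 or
  degree-4 expansion can represent; the sharpness of real tissue scattering
  is unknown, so `kappa` is an explicit parameter swept in tests, not a
  calibration claim.
* `scattering_strength = 0.15` per mm (mean over the sphere): with ~4 mm
  paths and the `4*pi/3` kernel scale this keeps simulated visibility
  reductions in the measurable range `d ~ 0.1..1`. (Strengths an order of
  magnitude higher drive `d` to the clipping floor and saturate the
  simulated signal — unphysical and unrecoverable, just as a real
  measurement of `d ~ 1e-11` would be.)
* detector at half-voxel pitch, 3n+1 pixels: real detectors resolve finer
  than the reconstructed grid, and the odd count provides an exact central
  ray for invariance checks.
* noise: multiplicative log-normal on `d` (additive Gaussian on `p`), the
  simplest model consistent with positive visibility; one seeded generator
  drives it, geometry is deterministic.

What the phantoms deliberately do not model: anatomically realistic
cerebellar geometry, gray-matter cellular microstructure, attenuation
cross-talk, detector physics beyond the multiplicative noise term. Passing
tests therefore demonstrate the correctness of the *chain* — model,
solver, transform, peak logic, tracking — under known ground truth, not
performance on real tissue.

## Numerical choices and degenerate inputs

* Joseph (slice-interpolating) line integrals, chosen over Siddon for
  smoother adjoint footprints; exact for axis-aligned rays through voxel
  centers; rays missing the grid contribute zero.
* Measured `d = 0` would make `p` infinite; simulation clips to
  `(1e-12, 1]` and reconstruction rejects non-finite sinograms.
* Underdetermined SH fits without regularization raise a rank-deficiency
  error rather than returning a minimum-norm fit silently.
* The icosphere is capped at subdivision 7 (~327k vertices) as a resource
  guard; antipode collapse matches exact floating-point negation pairs.
* Beam/grating frames within 1e-8 of parallel are rejected as degenerate.

## Problem sizes used in the checks

The end-to-end acceptance checks run a 32^3 volume, 80 poses, a 97^2
half-pitch detector and 100 CGLS iterations (about ten seconds of compiled
projector work per reconstruction on one core); unit tests use 8^3–16^3
instances of the same chain. These sizes were chosen so the full suite
exercises every stage, including two full reconstructions, at desk scale.

## Known limitations

* The squared-cosine kernel caps observability at degree 2; crossing
  fibers inside one voxel are only separable with the `"abs"` kernel (or
  externally supplied degree-4 volumes) and a sufficiently rich protocol.
* Orientation accuracy is quantized by the peak grid (~4 degrees at
  subdivision 4); subdivision 5 halves that at 4x the cost.
* CGLS with a fixed budget has no formal stopping criterion for noisy
  data; the residual history is exported so users can inspect
  semiconvergence.
* Streamline termination reasons are reported per half-track; no
  probabilistic tracking.
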