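# axdt — Anisotropic X-ray Dark-field Tomography

`axdt` is an R toolkit for imaging the *orientation* of fibrous
microstructure — aligned axon bundles in brain white matter being the
motivating case — from grating-interferometer X-ray dark-field measurements.
Nerve fibers are micrometer-scale, far below the resolution of the detector;
what the dark-field channel sees is the (ultra-)small-angle scattering they
produce, which is strongly anisotropic: a thin fiber scatters predominantly
orthogonal to its axis. By rotating the specimen fully in 3D on an Euler
cradle and recording how the visibility reduction changes with pose, the
scattering *profile* — a function on the sphere — can be reconstructed in
every voxel, and fiber directions extracted from it.

The package implements the whole chain on synthetic specimens:

1. **Forward model.** Each voxel `r` carries a scattering profile
   `eta(r, e)` expanded in real, orthonormal, even-degree spherical
   harmonics, `eta(r, e) = sum_k c_k(r) Y_k(e)`. For a pose with effective
   beam direction `l`, grating orientation `t` and sensitivity direction
   `s = l x t`, the log dark-field signal of a detector pixel is

       p = -log d = sum_k w_k(s) * integral of c_k along the pixel ray,

   with kernel weights `w_k(s) = ∫ Y_k(e) <e, s>^2 de` (Funk–Hecke closed
   form; only degrees 0 and 2 are observable under this kernel). Line
   integrals use a Joseph (slice-interpolating) projector with an exact
   adjoint, both in compiled code.
2. **Reconstruction.** CGLS on the linear log-domain system, with optional
   Tikhonov regularization, returning per-voxel SH coefficient volumes.
3. **Fiber extraction.** The Funk–Radon transform (diagonal in SH:
   degree-`l` blocks scale by `2*pi*P_l(0)`) turns plate-like scattering
   into a peak along the fiber axis; peaks are detected on an icosphere
   grid, masked by scattering strength and anisotropy, and tracked into
   streamlines with sign-aware bidirectional Euler integration.
4. **Phantoms.** Synthetic specimens (straight bundles, helices, crossing
   pairs, isotropic balls) with Watson-type girdle profiles
   `strength * N(kappa) * exp(-kappa <e, f>^2)`, plus simulated noisy
   acquisitions over quasi-uniform Euler-cradle protocols.

Volumes are written as multi-component NIfTI with JSON sidecars, sinograms
as NIfTI + protocol sidecar, streamlines as TCK, configs as YAML — all
openable in standard neuroimaging viewers.

## Worked example

```r
library(axdt)

# simulate a 32^3 straight fiber bundle (0.5 mm voxels, fiber along x)
# scanned over 80 Euler-cradle poses
fx <- make_fixture("straight", size = 32, seed = 1, noise_sigma = 0.01)
protocol_coverage(fx$protocol)   # worst sensitivity-direction gap (rad)
#> [1] 0.3454663

# reconstruct the degree-2 spherical-harmonics coefficient volume
rec <- reconstruct(fx$sinogram, fx$protocol, dims = rep(32, 3),
                   basis = sh_basis(2), n_iterations = 100, spacing = 0.5)
tail(rec$residual_history, 1)    # relative data residual after 100 CGLS its
#> [1] 0.00314868

# Funk-Radon transform + peak extraction -> per-voxel fiber orientations
field <- principal_orientation_field(funk_radon_volume(rec$volume),
                                     icosphere(4, collapse_antipodes = TRUE),
                                     magnitude_threshold = 0,
                                     anisotropy_threshold = 0.02)
orientation_error(field, fx$truth)$mean_deg  # vs ground truth, in-bundle
#> [1] 0.05100019
```

The residual says the reconstruction explains all but ~0.3% of the
simulated data; the mean angular error of ~0.05 degrees says the principal
extracted orientation in essentially every bundle voxel points along the
true fiber axis (the residual error is far below the ~4-degree resolution
of the peak grid because this fiber axis falls on a grid vertex; oblique
axes recover to within a vertex spacing).
`run_pipeline()` (or the CLI below) chains the same stages and writes all
artifacts to disk:

```sh
Rscript inst/cli/axdt.R pipeline --config config.yaml --out results/
```

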