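# fodflow

Contextual PDE enhancement of fiber orientation distributions (FODs) and
fiber-to-bundle coherence (FBC) filtering for diffusion-MRI tractography,
in R.

## The problem

High angular resolution diffusion imaging (HARDI) resolves crossing white
matter fiber bundles by estimating, in every voxel, a fiber orientation
distribution `U : R^3 x S^2 -> R+` — typically with constrained spherical
deconvolution (CSD). Noise, acquisition artifacts and partial-volume
effects corrupt these per-voxel estimates, and streamline tractography run
on them produces misaligned and spurious fibers. `fodflow` implements two
remedies that share one mathematical engine, a hypo-elliptic diffusion on
the coupled space of positions and orientations `R^3 x S^2` embedded in
the rigid-body-motion group:

```
dW/dt = ( D33 (n . grad_y)^2  +  D44 Lap_S2 ) W,     W(., ., 0) = U
```

Spatial diffusion acts only *along* the current orientation `n` (strength
`D33`), angular diffusion is isotropic on the sphere (strength `D44`), and
the diffusion time `t` sets how much spatial context is integrated. This
"contour enhancement" process strengthens aligned, elongated structures
while preserving crossings.

1. **FOD enhancement** — the PDE is applied to a CSD FOD field by
   *shift-twist convolution* with an analytic approximation of its
   Green's function `p_t(y, n)`, expressed in the moving frame of each
   source orientation. An explicit finite-difference evolver of the same
   PDE is included as an independent numerical cross-check.
2. **Fiber-to-bundle coherence** — a tractogram is turned into a density
   of oriented points (each streamline point with its tangent, antipodally
   doubled), diffused with the same kernel, and read back along each
   fiber. The local score (LFBC), its windowed minimum (FBC^alpha), the
   bundle average (AFBC) and the ratio RFBC = FBC^alpha / AFBC quantify
   how coherent each fiber's least coherent section is; thresholding RFBC
   at a fraction of its maximum removes spurious streamlines.

Around this core the package provides CSD (with non-negativity
constraint), a DTI-based FOD baseline, deterministic and probabilistic
tractography, Tractometer-style evaluation metrics (angular error of FOD
peaks, VC/IC/NC, ABC, CSR, VCCR), a synthetic phantom generator with
Rician noise, and NIfTI / bvec-bval / TCK input-output.

## Worked example

Simulate a 45-degree crossing phantom, estimate FODs with CSD at SNR 4,
enhance them, and compare the average angular error of the FOD peaks
against the ground truth:

```r
library(fodflow)

g1 <- bundle_geometry("straight", from = c(0, 8, 5), to = c(16, 8, 5), radius = 2)
c45 <- 8 * cos(pi / 4)
g2 <- bundle_geometry("straight", from = c(8 - c45, 8 - c45, 5),
                      to = c(8 + c45, 8 + c45, 5), radius = 2)
truth <- make_phantom(list(g1, g2), grid_shape = c(16, 16, 10), voxel_size = 1)

resp <- default_response(b_value = 3000)
grad <- fibonacci_directions(64)
dwi  <- simulate_dwi(truth, resp, grad, 3000, noise_model(snr = 4, rng_seed = 11))

fod  <- csd_fit_volume(dwi, resp, csd_config(l_max = 8), mask = truth$mask)
enh  <- enhance_fod(fod, enhancement_params(D33 = 1, D44 = 0.01, t = 2),
                    frequency = 4, half_width = 4)

dense <- make_icosphere(61)          # 18606 antipodally distinct directions
angular_error(fod, truth, dense)     # 12.29 degrees
angular_error(enh, truth, dense)     # 5.25 degrees
```

The two printed numbers are the mean angular distance (degrees, antipodal
identification) between each true fiber direction and the nearest FOD
peak, before and after enhancement: contextual regularization roughly
halves the peak error at this noise level. The same `enhancement_params`
engine scores streamlines:

```r
bundle <- sample_truth_fibers(truth, n_fibers = 20, step_mm = 1,
                              jitter_mm = 0.1, rng_seed = 7)
bundle <- inject_spurious(bundle, k = 5, lateral_offset_mm = 8,
                          angle_deg = 30, rng_seed = 8)
scores <- rfbc(bundle, enhancement_params(1, 0.04, 1.4), alpha_mm = 4)
range(scores[attr(bundle, "outlier_index")])   # 0.034 .. 0.047
range(scores[1:20])                            # 0.760 .. 1.120
filtered <- filter_bundle(bundle, scores, epsilon_fraction = 0.1)
length(filtered$fibers)                        # 20 — all outliers removed
```

A thin command-line wrapper over these functions lives in
`inst/cli/fodflow.R` (subcommands `csd`, `enhance`, `track`, `fbc`), and
`run_pipeline()` drives the whole chain from one seeded configuration.

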