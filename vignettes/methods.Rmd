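---
title: "Contextual enhancement of FOD fields and coherence-based streamline filtering: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, what the synthetic data emulate,
and the numerical decisions taken where a choice was genuinely open.

## 1. The diffusion model on positions and orientations

Diffusion-MRI orientation data live on the coupled space
$\mathbb{R}^3 \rtimes S^2$ of positions and orientations. Alignment of an
oriented element $(\mathbf{y}, \mathbf{n})$ with its neighborhood cannot
be judged by adding a Euclidean spatial distance and an angular distance:
moving *along* $\mathbf{n}$ must be cheap, moving sideways expensive, and
turning isotropic. Embedding the space in the rigid-body-motion group
supplies exactly this structure, and the contour-enhancement diffusion

$$
\partial_t W = \bigl( D_{33}\, (\mathbf{n}\cdot\nabla_{\mathbf{y}})^2
              + D_{44}\, \Delta_{S^2} \bigr) W, \qquad
W(\cdot,\cdot,0) = U,
$$

is its canonical crossing-preserving smoothing: hypo-elliptic (spatial
diffusion only along $\mathbf{n}$), well posed iff $D_{33}, D_{44} > 0$
(Hörmander condition, enforced by `enhancement_params()`).

**Parameters and units.** Spatial coordinates are in voxel units by
default (`voxel_scale` rescales); $D_{33}$ is then voxel$^2$ per unit
diffusion time, $D_{44}$ rad$^2$ per unit time, and $t$ dimensionless
diffusion time. Only $t$ and the ratio $D_{33}/D_{44}$ matter up to
rescaling of $t$. Defaults follow the regimes the method is normally run
in: $D_{33} = 1$ fixed; $D_{44} \in [0.005, 0.04]$ (larger = fatter
glyphs, better reorientation of peaks in curved bundles, at some loss of
angular sharpness); $t \in [0, 5]$ (more context, more smoothing). For
streamline coherence scoring the package default is
$D_{33}=1, D_{44}=0.04, t=1.4$, and for FOD enhancement before
probabilistic tracking $D_{33}=1, D_{44}=0.01, t=2$ with post-hoc
sharpening.

## 2. The analytic kernel and its discretization

The PDE is solved by shift-twist convolution with an approximate Green's
function: spatial offsets are expressed in the moving frame
$R_{\mathbf{n}'}$ of the source orientation, and the canonical z-aligned
kernel factorizes into two planar roto-translation kernels,

$$
p_t(\mathbf{y}, \mathbf{n}) \propto
p^{2D}_t(z/2,\, x,\, \beta)\; p^{2D}_t(z/2,\, -y,\, \gamma),
\qquad
p^{2D}_t(x, y, \theta) \propto e^{-EN(x, y, \theta)/(4t)},
$$

with $(\beta,\gamma)$ the angular coordinates of $\mathbf{n}$
(`to_beta_gamma()`), and $EN$ the weighted modulus of the planar group's
logarithmic coordinates
$c^1 = \mathrm{stab}(\theta)\,x + \theta y/2$,
$c^2 = -\theta x/2 + \mathrm{stab}(\theta)\,y$, $c^3 = \theta$:

$$
EN = \sqrt{\Bigl(\tfrac{(c^3)^2}{D_{44}} + \tfrac{(c^1)^2}{D_{33}}\Bigr)^2
          + \tfrac{(c^2)^2}{D_{33} D_{44}}},
\qquad
\mathrm{stab}(\theta) = \frac{\theta}{2\tan(\theta/2)}.
$$

`stab_factor()` switches to the Taylor series
$1 - \theta^2/12 - \theta^4/720 - \theta^6/30240 - \theta^8/1209600$
below $|\theta| = \pi/10$ to avoid cancellation; angles are wrapped to
$[-\pi, \pi)$ and clamped strictly inside (the kernel is vanishingly
small near $\pm\pi$).

**Properties of the approximation worth knowing.**

* The planar kernel is *exactly* invariant under the group inverse map
  (verified to machine precision in the tests).
* The 3D product kernel is only *approximately* axially symmetric:
  simultaneous rotation of $(\mathbf{y}, \mathbf{n})$ about $e_z$ changes
  values by up to $\sim$10–15% of the kernel maximum. Consequently the
  choice of $R_{\mathbf{n}'}$ (the package uses the minimal geodesic
  rotation, `rotation_to()`) matters at the same level; one convention is
  used consistently everywhere.
* The along-fiber spatial variance of the product kernel is $4 D_{33} t$,
  twice the $2 D_{33} t$ of the PDE itself — each planar factor
  contributes an independent along-fiber spread through its $z/2$
  argument. This is a property of the closed-form approximation, not a
  bug; the finite-difference evolver realizes the exact PDE rate. On
  smooth FOD-like inputs the two paths correlate at $r \approx 0.98$; on
  white-noise or delta inputs (not the method's input class) the
  difference in spatial scale lowers the correlation to $\approx 0.8$,
  which is why the oracle-equivalence test uses a crossing-bundle field.

**Discretization.** `build_kernel_lut()` evaluates the kernel
analytically for every source orientation of an icosphere sampling on a
cubic offset window $\{-h..h\}^3$. Scalar prefactors are superseded by
exact renormalization: each source slice is normalized to unit
quadrature mass, then an alternate scaling (Sinkhorn-style) balances the
target marginals so that the discrete convolution both conserves total
mass and preserves constants to $\sim 10^{-13}$. The default window
derives from the along-fiber standard deviation $2\sqrt{D_{33} t}$ so
that clipped tail mass stays below $10^{-3}$; for large $t$ this window
is expensive, and the pipelines instead fix $h = 4$–$5$ and renormalize
the (documented) clipped mass — peak locations are insensitive to this.
A window too small for the requested tolerance raises an error naming
the required half-width.

## 3. The finite-difference cross-check

`fd_evolve()` integrates the PDE by explicit Euler:
$(\mathbf{n}\cdot\nabla)^2$ by second-order central differences with
trilinear interpolation one voxel along $\pm\mathbf{n}$, and
$\Delta_{S^2}$ by a mass-lumped cotangent mesh Laplacian on the
tessellation (conserving quadrature-weighted mass exactly in the
symmetric form $M^{-1}C$). The step size is checked against a Gershgorin
bound on the generator's spectral radius and an unstable request is
refused with the maximal stable step named. The two realizations of the
same diffusion — closed-form convolution and FD integration — are
developed independently and cross-validated in the test suite.

## 4. CSD, the response function, and the DTI baseline

CSD solves, per voxel, iterated least squares
$\min_g \|K *_{S^2} g - S\|^2 + \lambda^2 \|L_{f^i}(g)\|^2$ where $L_h$
selects constraint directions whose previous-iterate amplitude falls
below $\tau$ times the mean amplitude (Heaviside selection) and drives
them to zero — a soft non-negativity constraint. The initial iterate is
the data-driven (lightly damped) solution; iteration stops when the
constraint set repeats (coefficient delta $<10^{-6}$ as numerical guard)
or at `i_max`. The deconvolution literature names $\tau$, $\lambda$,
`i_max` but their numeric values are tied to each implementation's
amplitude normalization. The package defaults are $\tau = 0.1$,
`i_max = 50`, constraint sampling = frequency-5 icosphere (252
directions, hemisphere view), and $\lambda = 4$: in this package's FOD
scale convention (Funk–Hecke factors $\sqrt{4\pi/(2l+1)}\,k_l$), a sweep
at SNR 10 showed $\lambda = 1$ leaves over 20% of constraint directions
meaningfully negative, while $\lambda \gtrsim 5$ suppresses negativity
below 1% but introduces constraint-induced Gibbs ringing (secondary
lobes above the 10% peak threshold on noiseless crossings). The default
$\lambda = 4$ keeps noiseless 90° and 45° crossings ripple-free at the
cost of $\approx 1.2\%$ residual negativity — an explicit trade-off of
the $l_{max} = 8$ band limit. All three parameters are
configuration-exposed. Convergence is typically
reached in 5–10 iterations and the per-voxel counts are logged.
Super-resolution is disabled: `l_max` is auto-capped so the coefficient
count never exceeds the measurement count (32 directions force
$l_{max}=6$, 28 coefficients).

The spherical convolution uses the Funk–Hecke factors
$\lambda_l = \sqrt{4\pi/(2l+1)}\, k_l$ of the zonal response; this fixes
the absolute FOD scale convention (peak locations are unaffected). The
sharpening deconvolution hook divides per-order coefficients by a zonal
kernel's factors (floored); `enhance_fod(sharpen = TRUE)` uses it to
deconvolve the enhancement's own angular blur $e^{-t D_{44} l(l+1)}$,
restoring angular sharpness while keeping the gained spatial context.

The DTI baseline maps a log-linear tensor fit through
$U_{DTI}(\mathbf{y},\mathbf{n}) \propto (\mathbf{n}^T D^{-1}
\mathbf{n})^{-3/2}$, normalized once by
$4\pi \int_\Omega \sqrt{\det D}$ over the analysis mask (voxel-volume
weighted sum); $\Omega$ = mask is this package's reading.

## 5. Spherical harmonics, tessellations, quadrature

The SH basis is real, orthonormal, even-order only, ordered
lexicographically in $(l, m)$ — tagged `real-sym-lex` in all coefficient
files, which refuse to load without the tag. Geodesic icospheres carry
the orientation samples: subdividing each icosahedron edge into $f$
segments gives $10f^2 + 2$ vertices closed under the antipodal map;
"frequency 61" yields 18606 antipodally distinct directions with
sub-degree resolution and is the dense grid used for peak extraction.
Quadrature weights are one third of each incident spherical triangle's
area. Exact spherical Voronoi cell areas were measured to integrate SH
products slightly *worse* on these meshes, so the simpler barycentric
dual is used; either way the SH Gram matrix at frequency 16 / order 8 is
identity to $\approx 2\times10^{-3}$ off-diagonal — the inherent
$O(h^2)$ quadrature error of vertex-area rules, which also bounds
quadrature-based oracles in the tests (e.g. the zonal-convolution
check at $10^{-3}$).

## 6. Tractography

Deterministic tracking follows, at each step of a tenth of a voxel, the
FOD peak most aligned with the incoming direction (antipodal sign
resolved forward), with the initial direction drawn among peaks within
`init_cutoff = 0.9` of the voxel's strongest; tracks run both ways from
the seed and terminate below an *absolute* cutoff of 10% of the field's
maximal angular response or at the volume boundary. Probabilistic
tracking samples tessellation directions inside the curvature cone
implied by a 1 mm minimal radius (turning angle
$\le 2\arcsin(\mathrm{step}/2r_{min})$), with probability proportional
to the positive FOD amplitude (quadrature-weighted). The literal rule
"terminate when total positive cone mass < cutoff × voxel max" compares
a quadrature-weighted mass ($\approx 0.05 \times$ max even for a
delta-sharp aligned lobe on a 642-direction tessellation) with a raw
amplitude and would stop every track at its first step; the package
instead applies the absolute amplitude cutoff inside the cone, matching
the deterministic rule. SH coefficients are interpolated trilinearly
(voxel centers at $(i+\tfrac12)\times$ spacing, 0-based half-open voxel
ownership everywhere). Peak directions are refined by an
amplitude-weighted mean within a 6° cone to suppress tessellation
quantization; per-seed RNG substreams are keyed on the seed position, so
results are independent of seed ordering. None of this claims bit-level
equivalence with any external tracker; parameters mirror the standard
settings (step = voxel/10, cutoff 0.1, initial cutoff 0.9, minimal
radius 1 mm).

## 7. Coherence scoring and filtering

Every streamline point contributes two delta distributions ($\pm$
tangent, handled by summing both source orientations rather than
duplicating storage). The diffused density is evaluated analytically at
the fiber points — the self term included exactly as the double sum is
written; it adds a constant offset that cancels in RFBC. Pairs beyond a
spatial cutoff (default $6\sqrt{D_{33} t}$, where the kernel is below
$\sim10^{-6}$ of its maximum) are skipped and the skip fraction logged;
an exact $O(N^2)$ mode is kept for tests (agreement to $10^{-4}$
relative). The window length $\alpha$ is configured in millimetres and
converted through the streamline step (integer windows
$a \in [0, N_i - \alpha]$, following the discrete index convention at
fiber ends); fibers shorter than $\alpha$ use their full length.
Filtering retains fibers with RFBC $\ge \epsilon \cdot
\max(\mathrm{RFBC})$; the arg-max fiber always survives. When a
tractogram subset must be selected first (e.g. "most anterior" fibers),
`select_extreme_fibers()` keys each fiber by the extreme of one
coordinate — the ordering key is explicit configuration, since no
canonical definition exists.

## 8. The synthetic phantoms — what they emulate and what they do not

`make_phantom()` rasterizes straight, circular-arc or spline tubes;
truth peaks are centerline tangents at the nearest curve point, merged
within 5°; endpoint ROIs are tube cross-sections within 2 voxels of the
curve ends. The forward signal model is the response-convolution one: a
voxel's noiseless signal is the weight-normalized sum of the zonal
single-fiber response rotated to each truth peak, with Rician noise
$\sqrt{(S + \sigma X)^2 + (\sigma Y)^2}$, $\sigma = 1/\mathrm{SNR}$
(SNR measured against the unit $b=0$ intensity). The default response is
the zonal fit of an axially symmetric tensor signal with eigenvalues
$(1.7, 0.2, 0.2)\times10^{-3}$ mm$^2$/s at the configured b-value —
standard single-fiber white-matter values.

This generator is deliberately self-consistent with CSD's own forward
model: passing the recovery tests shows correct inversion, regularization
and metric plumbing, *not* robustness to model mismatch (restricted
compartments, sub-voxel dispersion, partial volume with non-fiber
tissue, spatially varying response), which real data exhibit. Background
voxels carry an isotropic signal (mean diffusivity $0.7\times10^{-3}$
mm$^2$/s) so that tracking terminates outside bundles.

## 9. Problem sizes and reference conditions

The validation suite runs, by the package's own choice of desk-scale
conditions: the 45° crossing phantom on a $16\times16\times10$ 1 mm grid
with 2 mm tubes, 64 Fibonacci gradients at $b = 3000$ s/mm², SNR
$\in \{\infty, 4\}$ (noiseless peak error $\approx 1^\circ$; at SNR 4
enhancement with $t = 2$ roughly halves the error); the oracle
equivalence on an $8^3$ grid with 162 orientations at
$D_{33}=1, D_{44}=0.02, t=1$; coherence filtering on a 20-fiber straight
bundle (30 mm, 1 mm tube) with 5 outliers offset 8 mm
($\gg \sqrt{D_{33}t} \approx 1.2$ mm); and the stability experiment on a
quarter-arc bundle (radius 8 mm, tube 1.5 mm) at SNR 10, ten seeded
repetitions of 60-streamline probabilistic tracking, comparing the
standard deviation of the bundle-tip-to-target distance before tracking
on the plain CSD FOD versus after enhancement plus RFBC filtering at
$\epsilon = 0.05\,\epsilon_{max}$.

## 10. Known limitations

* The analytic kernel is a *basic approximation*: approximate axial
  symmetry and a doubled along-fiber variance, as quantified above.
* Nonlinear, data-adaptive, or erosion-type PDE processing is out of
  scope, as are multi-shell / recursive-calibration CSD variants and
  super-resolution.
* Enhanced FODs are not clipped to nonnegative before refitting by
  default (`clip_negative` exposes the choice and it is recorded in the
  output); probabilistic tracking clips negative amplitudes at sampling
  time.
* The connection classifier is a documented simplification (endpoint
  ROI pairs); it does not reimplement full bundle-recognition
  heuristics, and edge rules for loops re-entering a ROI are the
  package's own.
* TCK is the only streamline dialect; NIfTI volumes are written with a
  diagonal (spacing-only) affine, world coordinates in mm, RAS.
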