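---
title: "Methods: fan-beam photoacoustic tomography with a rotating arc array"
author: "fanpat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fan-beam photoacoustic tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fanpat)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, and the numerical and design choices behind them.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## Scanner model and coordinate frame

The instrument is a concave 384-element transducer arc (11.5 cm long,
radius of curvature 12 cm) on a spherical dome that rotates rigidly about
its symmetry axis, acquiring one radio-frequency (RF) plane per pose
(default 200 poses at 1.8°, 40 MHz sampling, 1500 m/s assumed sound speed).
We place the origin at the dome's centre of curvature with *z* along the
rotation axis pointing away from the dome opening; the pose-0 imaging plane
is the *x–z* plane, so every pose is a single rotation about *z*
(`rotatePose`).  Element normals point at the dome centre; the lateral
direction is the arc tangent toward increasing element index; elevational
completes the right-handed triad.

Two geometric quantities are not derivable from the published arc layout
and are configurable defaults:

* **Elevational element aperture** (0.5 cm): fixes the element area that
  enters the solid-angle weights.  Only *relative* weights matter because
  the back-projection normalizes by the per-voxel weight sum, so this
  choice rescales nothing observable.
* **Arc centre polar angle** (27.5° from the apex): positions the arc
  between apex and rim, matching a dome whose 18-cm opening subtends about
  49°.

## Acoustic forward model

A wire phantom is discretized into point-source chains at quarter-voxel
spacing (`wireSources`); each point carries `μa · πr² · Δs`.  A source at
`r` contributes to element `rD` a wavelet delayed by `|r − rD|/vs`, scaled
by `Ψ(r)·μa(r)·S0(θL,θE)/|r − rD|` (spherical spreading; acoustic
attenuation is omitted, as is standard for cm-scale soft-tissue PAT at
these frequencies).

**Wavelet shape.**  The source wavelet is the first derivative of a
Gaussian — the N-shaped wave a point absorber actually radiates — with its
spectral peak at the configurable centre frequency (default 5 MHz, inside
the DAQ's 2–20 MHz band) and exact sub-sample placement (the wavelet is
evaluated continuously, not shifted on the sample grid).  This choice is
load-bearing: the universal back-projection integrand `p − t·∂p/∂t` peaks
at the geometric delay only when the measured arrival is
derivative-shaped.  A symmetric (even) pulse makes the dominant `−t·∂p/∂t`
term antisymmetric about the true radius and visibly destroys lateral
localization.  Consequently the per-channel *signal* peak sits within a
half-lobe (≈ 2 samples at 40 MHz) of the nominal delay rather than exactly
on it; tests assert that form.

**Structured noise** (`noiseModel`) emulates what the SVD stage exists to
remove: each band is a low-rank outer product of a smooth cross-channel
profile and a temporal burst; white noise and per-pulse energy jitter
(uniform ±12.5%, the middle of the 10–15% shot-to-shot variability the
laser exhibits) complete the model.  The jitter multiplies the plane *and*
is recorded in its `pulseEnergy`, which is what makes energy normalization
testable.  All draws flow through one seeded generator; a fixed seed gives
bitwise-identical scans.

## Optical fluence under the diffusion approximation

The fluence of a point source in a homogeneous scattering medium is

\[ \Psi(r) = \frac{e^{-\mu_{\mathrm{eff}} r}}{4\pi D r}, \qquad
   D = \frac{1}{3(\mu_{a0} + \mu_s')}, \quad
   \mu_{\mathrm{eff}} = \sqrt{\mu_{a0}/D}, \]

valid when absorption is small against reduced scattering;
`opticalProperties` sets an advisory flag when `μa0 > 0.1 μs'`.  Reference
values: breast tissue at 700 nm (`μa0 = 0.2`, `μs = 10` cm⁻¹) and the
50/50 milk/water calibration bath (`μa0 = 0.0075`, `μs = 15` cm⁻¹).  The
anisotropy `g` defaults to 0 — the quoted coefficients are treated as
already-reduced scattering, because they are used directly in the diffusion
relations; a nonzero `g` reinterprets them as raw `μs`.

**Fan-beam quadrature.**  The fan (90° × 0.24° divergence) illuminates a
band `B` of the dome surface; the fluence at a voxel is the kernel
integrated over `B` in the two divergence angles, discretized into
`nPatches = 200` patches *uniform in the fan angles* `(θ, ϕ)`.  Patch
centres are ray–sphere intersections from the virtual source point; each
patch carries the angular element `Δθ·Δϕ` as its quadrature weight.  We
considered weighting patches by their dome surface *area* instead; that
corresponds to a different integral (the Jacobian grows toward the window
ends, where the rays strike obliquely and the source is farther) and
produces a window profile peaked at the window *ends*, contradicting the
centre-peaked profile a uniform-per-angle engineered diffuser delivers.
The angular measure is therefore the one implemented.  Quadrature
convergence (successive refinements shrink) and the degenerate single-patch
identity are tested.

**Numerical guards.**  Distances below half a voxel are floored (the 1/r
kernel is singular on the surface).  Because the illuminator is fixed to
the transducer, one `FluenceVolume` is computed per pose; caches
(`computeFluenceCache`) let the four-variant comparison reuse them.
Fluence units are relative throughout — the estimate's absolute scale is
declared arbitrary, matching an instrument whose per-pulse energy is only
known relatively.

## Preprocessing

Fixed order, each step per-plane and stateless:

1. **Butterworth low-pass**, order 5, cutoff 14.5 MHz, applied
   forward–backward (zero phase) so arrival times used by back-projection
   survive; a single-pass causal mode exists for completeness.  Edges are
   reflect-padded by several filter lengths.  Low-frequency content is
   deliberately retained here — the band noise lives there and the SVD
   stage needs it; the ramp filter removes it later.
2. **Truncated-SVD denoising**, default k = 10 discarded singular values
   (the published operating point for this scanner's data).  The removed
   rank-k matrix is returned, so `output + removed = input` holds exactly;
   the report records the Frobenius energy fraction removed and flags
   planes where that exceeds 90%.
3. **Energy normalization** by `reference / pulseEnergy`.  The reference
   defaults to the scan-mean energy (the instrument has no absolute
   standard to normalize to; the mean preserves the overall scale).

## Reconstruction

Per voxel `r`, the estimate is the weighted mean over elements of the
ramp-filtered signal `b(t) = p − t·∂p/∂t` (central differences, one-sided
at the ends, `t = 0` at the laser firing) interpolated linearly at
`t = |r − rD|/vs`; nearest-neighbour interpolation exists for oracle
parity.  Weights are the element solid angle `A·cosγ/d²` (clipped to 0 for
back-facing voxels) times, optionally, the measured separable Gaussian
directivity `exp(−θL²/2σL²)·exp(−θE²/2σE²)` with σL = 18.5°, σE = 6.2°.
Dividing by the per-voxel weight sum realizes the `2/Ω0` prefactor as a
weighted average — the absolute pressure scale is arbitrary, and the
weighting mitigates the partial-view bias of a non-enclosing aperture.
Negative values are retained; display thresholds belong to evaluation, not
reconstruction.

**Fluence compensation** divides each pose's pressure volume by that pose's
fluence map before accumulating.  Voxels with `Ψ < ε·max(Ψ)` (default
ε = 0.01) are masked rather than amplified — the model predicts essentially
no light there, so the division is pure noise gain; masked counts are
tallied in the volume's `info`.  The ε-mask interacts with the optical
regime: under breast-tissue attenuation (`μeff ≈ 2.47 cm⁻¹`) the 1%
threshold corresponds to ≈ 1.9 cm of usable dynamic range below the lit
surface, so depth-resolved compensation experiments are run under the
calibration bath (`μeff ≈ 0.58 cm⁻¹`, ≈ 8 cm of range) — which is also the
medium the physical calibration phantom was imaged in.

The compiled kernel iterates elements outermost so each element's sample
vector stays cache-resident while per-voxel accumulators stream; the
reduction order is fixed, so results are bitwise stable.  A literal R
triple-loop transcription of the weighted sum, built only from the exported
geometry primitives, serves as the oracle the kernel must match to 1e-9 on
16³ instances.

## Evaluation

* **SNR/FWHM**: peak region = contiguous run above half the profile
  maximum containing the argmax; SNR = mean peak amplitude over the
  standard deviation of all image amplitudes (peak included — exclusion is
  available but off), in dB as `20·log10` (amplitude convention).
* **Relative image error**: `‖A − M‖₂ / ‖M‖₂` after scaling each volume to
  unit maximum (reconstructions are in arbitrary units, the model is
  binary; policies `unit-norm` and `none` are available).  Note `a = 2m`
  gives 1 only under `none` — normalization exists precisely to remove
  that scale dependence.
* **Depth shells**: 50 equal-width bins in depth below the dome surface
  (`12 − |r|`); per-shell numerator/denominator sums are kept so shells
  recombine exactly to the global error; shells without model content are
  `NA`, not 0.
* **SSIM**: Wang-style windowed form with a Gaussian window (σ = 1.5,
  truncated at 3.5σ, edge replication), `K1 = 0.01`, `K2 = 0.03`,
  uncorrected local covariances, border of one window radius cropped
  before averaging — the same recipe as the reference scikit-image
  implementation, against which a frozen fixture value is tested.  SSIM of
  a full contrast inversion is negative only for locally zero-mean images;
  with nonzero local means the luminance term flips sign too and the
  product is positive, which the checkerboard fixture demonstrates.

## What the simulator does and does not establish

The generator reproduces the *mechanisms* the pipeline exists to handle:
geometric delays, spherical spreading, directional sensitivity, rotating
non-uniform illumination, low-rank band noise, energy jitter.  It omits
acoustic heterogeneity and refraction, frequency-dependent element
responses, the three-way 128-channel multiplexing, reverberation, and any
mismatch between the fluence model and real light transport — in the
simulation the compensation divides by the *same* model that generated the
data, so compensation experiments here demonstrate internal consistency
and algorithmic benefit, not that the diffusion approximation is adequate
for a given tissue.

## Problem sizes used by the tests

Chosen so the whole suite runs in minutes on one CPU: oracle equivalence
on 8 elements × 16³ voxels × 64 samples; localization on 10 random point
sources, 64 elements, 32 poses, a 64³ grid at 1 mm with the wavelet centre
frequency lowered to 0.25 MHz so the reconstructed point spread
(width ≈ `vs/(2π fc)`) spans about one voxel — on a grid that undersamples
the wavelet the argmax criterion would measure lattice luck, not the
algorithm; the four-variant depth comparison on two slanted wires
(depths ≈ 0.5–3 cm), 64 elements, 16 poses, 49×49×35 voxels at 1 mm, 50
shells; SVD checks at the DAQ's native 128×2080 shape.

## Known limitations

Delta electrical and temporal impulse responses (no deconvolution stage);
homogeneous sound speed and optics; no iterative or regularized inversion;
fluence modelled, never estimated from data; the CLI accepts YAML only.
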