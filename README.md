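# fanpat

Photoacoustic tomography (PAT) for a rotating arc-array breast scanner with
a fan-shaped diffuse illuminator.

## The problem

In photoacoustic tomography a nanosecond laser pulse deposits optical energy
in tissue; absorbing structures (blood vessels, dyed wire phantoms) heat,
expand, and radiate ultrasound that an array of detectors records.  The
initial acoustic pressure is proportional to the product of the local
optical fluence and the absorption coefficient,

    p0(r) ∝ Ψ(r) · μa(r),

so an image of `p0` only becomes an image of the absorption `μa` — the
quantity of biological interest — if the fluence `Ψ(r)` is known or
uniform.

This package targets a scanner where uniformity is impossible by
construction: a 384-element transducer arc (11.5 cm long, radius of
curvature 12 cm) embedded in a spherical dome that rotates through 360° in
200 steps of 1.8°, illuminated by a narrow fan-shaped beam (90° × 0.24°
divergence) entering through an optical window next to the array.  The
light diverges strongly between the window and the tissue, and the whole
illumination pattern rotates with the array, so `Ψ` must be re-modelled at
every tomographic pose and divided out during accumulation.

## What the package implements

- **Simulator** (`simulateScan`): wire/rod phantoms voxelized or discretized
  into point-source chains; a band-limited N-shaped source wavelet delayed
  by time of flight with 1/r spreading and Gaussian element directivity;
  structured noise (low-rank cross-channel bands, white noise, pulse-energy
  jitter).
- **Preprocessing** (`preprocessScan`): zero-phase order-5 Butterworth
  low-pass at 14.5 MHz, truncated-SVD removal of the leading k = 10 singular
  components (the band noise), and per-pulse energy normalization — in that
  order.
- **Fluence model** (`fluenceMap`): diffusion-approximation kernel
  `Ψ(r) = exp(−μeff r) / (4πDr)` integrated over the illuminated window
  band by patch quadrature (200 patches, uniform in the fan's divergence
  angles), with `D = 1/(3(μa0 + μs'))` and `μeff = sqrt(μa0/D)`.
- **Reconstruction** (`reconstructScan`): universal back-projection — the
  ramp-filtered term `p − t·∂p/∂t` interpolated at `t = |r − rD|/vs`,
  weighted by the element solid angle `dΩ0 = A·cosγ/d²` and optionally by
  the measured Gaussian directivity (σL = 18.5°, σE = 6.2°), normalized by
  the per-voxel weight sum; per-pose fluence compensation with an ε-mask
  against division by vanishing light.
- **Metrics** (`snrFwhm`, `rmse`, `ssim`, `imageError`, `depthError`,
  `compareVariants`): half-maximum peak SNR/FWHM, windowed SSIM, relative
  two-norm image error against a phantom model, and 50 equal-width depth
  shells resolving error versus imaging depth for the four reconstruction
  variants (± directivity, ± illumination compensation).

A thin CLI over these functions is installed at `inst/cli/fanpat.R`
(`simulate | preprocess | fluence | reconstruct | evaluate | run | fixture`),
driven by a single YAML config whose defaults are the scanner's stated
parameters (`readRunConfig`, `makeFixture`).  RF scans travel as NIfTI +
JSON sidecar containers; volumes as NIfTI.

## Worked example

A reduced scan of the bundled three-wire phantom in a 50/50 milk/water
bath, reconstructed with directivity weighting and fluence compensation:

```r
library(fanpat)

geom    <- buildArray(64)                    # reduced 64-element arc
illum   <- buildIlluminator()
bath    <- opticalProperties(0.0075, 15)     # 50/50 milk/water at 700 nm
phantom <- phantomFixture("three_wire")      # wires at ~1, 2, 3 cm depth
grid    <- voxelGrid(c(-2, -2, 7.9), 0.1, c(41L, 41L, 41L))
plan    <- acquisitionPlan(nAngles = 16L, angularStep = 22.5,
                           nSamples = requiredSamples(geom, grid,
                                        acquisitionPlan(nSamples = 2L)))

scan <- simulateScan(phantom, geom, illum, plan, optics = bath,
                     directivity = directivityModel(),
                     noise = noiseModel(bandAmplitude = 2e-10,
                                        whiteSigma = 5e-11, seed = 1))
pp  <- preprocessScan(scan, k = 10)
rec <- reconstructScan(pp$scan, grid, illum = illum, optics = bath,
                       directivity = directivityModel(),
                       compensation = TRUE)

pp$report
#> DenoiseReport: rank 10 discarded, 95.5% energy removed [flagged]
rec
#> ReconVolume (absorption, compensation: fluence, directivity):
#>   41 x 41 x 41, range [-0.00351, 0.00692]

pr <- extractProfile(rec, c(-2, 0, 10), c(2, 0, 10), n = 161)
m  <- snrFwhm(abs(pr$values), abs(values(rec)), pr$spacing)
sprintf("middle wire: SNR %.1f dB, FWHM %.2f mm", m$snr_db, m$fwhm)
#> [1] "middle wire: SNR 24.9 dB, FWHM 1.00 mm"
```

The denoise report is `[flagged]` because the injected band noise spans the
whole trace while the wire arrivals are sparse, so most of the raw
Frobenius energy really is noise.  The profile across the 2-cm-deep wire
recovers a 0.25 mm wire as a 1.0 mm peak — the resolution is set by the
wavelet and the reduced aperture, not the wire.  The `ReconVolume` is
tagged with what produced it: an absorption-mode image, fluence
compensated, directivity weighted.

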