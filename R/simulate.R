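## Acoustic forward model and structured-noise synthesis.
##
## The initial pressure at a source point is proportional to the local
## fluence times the absorption (p0 ~ psi * mu_a); each detector element sees
## that source delayed by distance / sound speed, scaled by spherical
## spreading 1/d and the element's Gaussian directional sensitivity, as a
## band-limited wavelet.  Acoustic attenuation is omitted.

#' Construct an RF plane
#'
#' @param samples channels x time matrix of pressure samples (arbitrary
#'   units); the channel count must equal the array's element count.
#' @param poseAngle tomographic pose angle, degrees.
#' @param pulseEnergy per-pulse energy in mJ (default 1).
#' @param samplingRate DAQ sampling rate, Hz.
#' @return An `RFPlane`.
#' @export
rfPlane <- function(samples, poseAngle = 0, pulseEnergy = 1,
                    samplingRate = 40e6) {
  new("RFPlane", poseAngle = poseAngle, samples = as.matrix(samples),
      pulseEnergy = pulseEnergy, samplingRate = samplingRate)
}

setMethod("rfSamples", "RFPlane", function(x) x@samples)
setMethod("rfSamples<-", "RFPlane", function(x, value) {
  x@samples <- value; validObject(x); x
})
setMethod("poseAngle", "RFPlane", function(x) x@poseAngle)
setMethod("pulseEnergy", "RFPlane", function(x) x@pulseEnergy)
setMethod("planes", "RFScan", function(x) x@planes)
setMethod("show", "RFPlane", function(object) {
  cat(sprintf("RFPlane: %d channels x %d samples @ pose %.1f deg, E=%.3g mJ\n",
              nrow(object@samples), ncol(object@samples), object@poseAngle,
              object@pulseEnergy))
})
setMethod("show", "RFScan", function(object) {
  cat(sprintf("RFScan: %d pose(s), %d elements, %d samples @ %.0f MHz\n",
              length(object@planes), object@geometry@nElements,
              object@plan@nSamples, object@plan@samplingRate / 1e6))
})

#' Structured-noise model for simulated RF data
#'
#' Band noise is synthesized as low-rank outer products of a smooth
#' cross-channel profile and a temporal burst (the horizontal "bands" that
#' dominate the first singular values of real RF matrices), plus white noise.
#' Per-pulse energy jitter multiplies the whole plane and is recorded in the
#' plane's `pulseEnergy`, emulating shot-to-shot laser variability (on the
#' order of 10--15%).
#'
#' @param bandCount number of noise bands (default 3).
#' @param bandRank rank per band (default 1).
#' @param bandAmplitude band amplitude in sample units (default 1).
#' @param whiteSigma white-noise standard deviation in sample units
#'   (default 0).
#' @param energyJitter half-range of the uniform relative energy jitter
#'   (default 0.125, the middle of the observed 10--15% variability).
#' @param seed integer RNG seed; fixed seed gives bitwise-identical noise.
#' @return A `NoiseModel`.
#' @export
noiseModel <- function(bandCount = 3L, bandRank = 1L, bandAmplitude = 1,
                       whiteSigma = 0, energyJitter = 0.125, seed = 1L) {
  new("NoiseModel", bandCount = as.integer(bandCount),
      bandRank = as.integer(bandRank), bandAmplitude = bandAmplitude,
      whiteSigma = whiteSigma, energyJitter = energyJitter,
      seed = as.integer(seed))
}

#' Forward-model the RF acquisition for one pose
#'
#' @param phantom a [phantomModel()], or a `ReconVolume`/3D array of
#'   absorption values (every non-zero voxel becomes a point source).
#' @param geom an [buildArray()] geometry at the desired pose.
#' @param plan an [acquisitionPlan()].
#' @param fluence per-source fluence: `NULL` for uniform illumination, a
#'   numeric vector (one value per source point), or a
#'   [FluenceVolume][fluenceMap] to interpolate.
#' @param directivity a [directivityModel()] applied as the element
#'   sensitivity `S0(thetaL, thetaE)` in the forward direction, or `NULL`.
#' @param pulseFc centre frequency of the band-limited source wavelet, Hz;
#'   default 5e6 sits inside the DAQ's 2--20 MHz band.  The wavelet is the
#'   first derivative of a Gaussian, the N-shaped wave a point absorber
#'   radiates, so the ramp-filtered back-projection peaks at the geometric
#'   delay.
#' @param grid a [voxelGrid()]; only needed when `phantom` is a volume.
#' @param sourceStep wire discretization step in cm (see [wireSources()]).
#' @return An `RFPlane` at the geometry's pose.
#' @export
forwardRF <- function(phantom, geom, plan, fluence = NULL, directivity = NULL,
                      pulseFc = 5e6, grid = NULL, sourceStep = 0.0125) {
  if (is(phantom, "PhantomModel")) {
    src <- wireSources(phantom, sourceStep)
  } else {
    vals <- if (is(phantom, "ReconVolume")) phantom@values else phantom
    if (is(phantom, "ReconVolume")) grid <- phantom@grid
    if (is.null(grid)) stop("grid is required for a volume phantom")
    nz <- which(vals != 0)
    vox <- voxelCenterMatrix(grid)
    src <- list(positions = vox[nz, , drop = FALSE],
                strengths = vals[nz] * grid@spacing^3)
  }
  psi <- .sourceFluence(src, fluence)
  amp <- src$strengths * psi
  vs_cm <- plan@soundSpeed * 100
  ## coverage check: farthest source must arrive inside the time window
  if (nrow(src$positions) > 0) {
    dmax <- 0
    for (e in seq_len(geom@nElements)) {
      d2 <- (src$positions[, 1] - geom@positions[e, 1])^2 +
            (src$positions[, 2] - geom@positions[e, 2])^2 +
            (src$positions[, 3] - geom@positions[e, 3])^2
      dmax <- max(dmax, max(d2))
    }
    if (sqrt(dmax) / vs_cm * plan@samplingRate > plan@nSamples - 1)
      stop("time window too short for the farthest source; increase nSamples",
           " (see requiredSamples())")
  }
  useDir <- !is.null(directivity) && directivity@enabled
  X <- forward_rf_kernel(src$positions, amp, geom@positions, geom@normals,
                         geom@laterals, plan@nSamples, plan@samplingRate,
                         vs_cm, pulseFc,
                         if (useDir) deg2rad(directivity@sigmaL) else -1,
                         if (useDir) deg2rad(directivity@sigmaE) else -1)
  rfPlane(X, poseAngle = geom@poseAngle, pulseEnergy = 1,
          samplingRate = plan@samplingRate)
}

.sourceFluence <- function(src, fluence) {
  n <- nrow(src$positions)
  if (is.null(fluence)) return(rep(1, n))
  if (is(fluence, "FluenceVolume"))
    return(interpVolume(fluence@values, fluence@grid, src$positions))
  if (length(fluence) == 1) return(rep(fluence, n))
  if (length(fluence) != n) stop("fluence length must match the source count")
  as.numeric(fluence)
}

#' Trilinear interpolation of a voxel volume
#'
#' @param vals 3D array of voxel values.
#' @param grid the [voxelGrid()] the array lives on.
#' @param pts n x 3 matrix of query points (cm); points outside the grid
#'   return 0.
#' @return Numeric vector of interpolated values.
#' @export
interpVolume <- function(vals, grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  u <- sweep(pts, 2, grid@origin) / grid@spacing   # 0-based voxel coords
  d <- grid@dim
  out <- numeric(nrow(pts))
  ok <- u[, 1] >= -1e-9 & u[, 2] >= -1e-9 & u[, 3] >= -1e-9 &
        u[, 1] <= d[1] - 1 + 1e-9 & u[, 2] <= d[2] - 1 + 1e-9 &
        u[, 3] <= d[3] - 1 + 1e-9
  i0 <- pmin(pmax(floor(u), 0), matrix(d - 2L, nrow(u), 3, byrow = TRUE))
  f <- u - i0
  if (any(ok)) {
    ii <- i0[ok, , drop = FALSE] + 1L               # 1-based corner
    fx <- f[ok, 1]; fy <- f[ok, 2]; fz <- f[ok, 3]
    at <- function(dx, dy, dz)
      vals[cbind(ii[, 1] + dx, ii[, 2] + dy, ii[, 3] + dz)]
    out[ok] <-
      at(0L, 0L, 0L) * (1 - fx) * (1 - fy) * (1 - fz) +
      at(1L, 0L, 0L) * fx * (1 - fy) * (1 - fz) +
      at(0L, 1L, 0L) * (1 - fx) * fy * (1 - fz) +
      at(1L, 1L, 0L) * fx * fy * (1 - fz) +
      at(0L, 0L, 1L) * (1 - fx) * (1 - fy) * fz +
      at(1L, 0L, 1L) * fx * (1 - fy) * fz +
      at(0L, 1L, 1L) * (1 - fx) * fy * fz +
      at(1L, 1L, 1L) * fx * fy * fz
  }
  out
}

#' Add structured noise to an RF plane
#'
#' @param plane an [rfPlane()].
#' @param noise a [noiseModel()]; zero amplitudes give the identity.
#' @param seed RNG seed (defaults to the model's own seed); the output is
#'   bitwise-reproducible for a fixed seed.
#' @return The noisy `RFPlane`, with `pulseEnergy` scaled by the jitter draw.
#' @export
addNoise <- function(plane, noise, seed = noise@seed) {
  X <- plane@samples
  nch <- nrow(X); ns <- ncol(X)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  jit <- if (noise@energyJitter > 0)
    runif(1, -noise@energyJitter, noise@energyJitter) else 0
  X <- X * (1 + jit)
  fs <- plane@samplingRate
  tt <- (seq_len(ns) - 1) / fs
  if (noise@bandAmplitude > 0) {
    for (b in seq_len(noise@bandCount)) {
      for (r in seq_len(noise@bandRank)) {
        c0 <- runif(1, 1, nch)
        w <- runif(1, nch / 20, nch / 4)
        prof <- exp(-0.5 * ((seq_len(nch) - c0) / w)^2)
        f0 <- runif(1, 0.5e6, 6e6)
        tc <- runif(1, 0.1, 0.9) * tt[ns]
        tau <- runif(1, 0.05, 0.3) * tt[ns]
        burst <- sin(2 * pi * f0 * tt + runif(1, 0, 2 * pi)) *
          exp(-0.5 * ((tt - tc) / tau)^2)
        X <- X + noise@bandAmplitude * (prof %o% burst)
      }
    }
  }
  if (noise@whiteSigma > 0)
    X <- X + matrix(rnorm(nch * ns, sd = noise@whiteSigma), nch, ns)
  rfPlane(X, poseAngle = plane@poseAngle,
          pulseEnergy = plane@pulseEnergy * (1 + jit),
          samplingRate = plane@samplingRate)
}

#' Simulate a full tomographic scan
#'
#' Rotates the array and illuminator rigidly through the acquisition plan,
#' recomputes the fluence at the wire sources for every pose (the illuminator
#' is fixed to the transducer, so the light pattern rotates with it), runs
#' the acoustic forward model and optionally adds structured noise.
#'
#' @param phantom a [phantomModel()].
#' @param geom pose-0 [buildArray()] geometry.
#' @param illum pose-0 [buildIlluminator()] geometry.
#' @param plan an [acquisitionPlan()].
#' @param optics [opticalProperties()] for the fluence model, or `NULL` for
#'   uniform illumination.
#' @param directivity [directivityModel()] for the forward model, or `NULL`.
#' @param noise [noiseModel()] or `NULL` for noise-free planes.
#' @param pulseFc source wavelet centre frequency, Hz.
#' @param nPatches fluence quadrature patches per pose.
#' @param sourceStep wire discretization step, cm.
#' @return An `RFScan` with one `RFPlane` per pose (`poseAngle = k *
#'   angularStep`).
#' @examples
#' geom <- buildArray(16)
#' plan <- acquisitionPlan(nAngles = 2, nSamples = 1200)
#' scan <- simulateScan(phantomFixture("point_source"), geom,
#'                      buildIlluminator(), plan)
#' length(planes(scan))
#' @export
simulateScan <- function(phantom, geom, illum, plan, optics = NULL,
                         directivity = NULL, noise = NULL, pulseFc = 5e6,
                         nPatches = 200L, sourceStep = 0.0125) {
  src <- wireSources(phantom, sourceStep)
  out <- vector("list", plan@nAngles)
  for (k in seq_len(plan@nAngles)) {
    ang <- (k - 1) * plan@angularStep
    gk <- rotatePose(geom, ang)
    ik <- rotatePose(illum, ang)
    psi <- if (is.null(optics)) NULL else
      fluenceAtPoints(src$positions, ik, optics, nPatches)
    pl <- forwardRF(phantom, gk, plan, fluence = psi,
                    directivity = directivity, pulseFc = pulseFc,
                    sourceStep = sourceStep)
    if (!is.null(noise)) pl <- addNoise(pl, noise, seed = noise@seed + k - 1L)
    out[[k]] <- pl
  }
  new("RFScan", planes = out, plan = plan, geometry = geom,
      illuminator = illum)
}
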