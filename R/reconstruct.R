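## Universal back-projection with solid-angle and directivity weighting, and
## per-pose fluence compensation.
##
## Per voxel r the inversion evaluates a weighted mean over detector
## positions rD of the ramp-filtered signal
##   b(t) = pD(rD, t) - t * dpD/dt     at t = |r - rD| / vs,
## with weights dOmega0 = A cos(gamma) / d^2 times the separable Gaussian
## directivity S0(thetaL, thetaE).  Normalizing by the per-voxel weight sum
## realizes the 2/Omega0 prefactor up to an (arbitrary) global scale.

#' Gaussian transducer directivity
#'
#' The measured directional sensitivity of the lensed array elements is
#' Gaussian in the lateral and elevational angles, with standard deviations
#' of 18.5 and 6.2 degrees respectively.
#'
#' @param sigmaL lateral standard deviation, degrees (default 18.5).
#' @param sigmaE elevational standard deviation, degrees (default 6.2).
#' @param enabled logical; a disabled model weighs every angle 1.
#' @return A `DirectivityModel`.
#' @export
directivityModel <- function(sigmaL = 18.5, sigmaE = 6.2, enabled = TRUE) {
  new("DirectivityModel", sigmaL = sigmaL, sigmaE = sigmaE, enabled = enabled)
}

#' @rdname directivityModel
#' @param thetaL,thetaE angles in degrees (vectorized).
#' @param model a `DirectivityModel`.
#' @return `directivityWeight` returns
#'   `exp(-thetaL^2/(2 sigmaL^2)) * exp(-thetaE^2/(2 sigmaE^2))`, or 1
#'   everywhere when the model is disabled.
#' @export
directivityWeight <- function(thetaL, thetaE, model) {
  if (!model@enabled) return(rep(1, length(thetaL)))
  exp(-thetaL^2 / (2 * model@sigmaL^2)) * exp(-thetaE^2 / (2 * model@sigmaE^2))
}

setMethod("show", "DirectivityModel", function(object) {
  cat(sprintf("DirectivityModel: sigmaL=%.1f deg, sigmaE=%.1f deg%s\n",
              object@sigmaL, object@sigmaE,
              if (object@enabled) "" else " (disabled)"))
})

#' Ramp-filter term of the back-projection integrand
#'
#' Computes `b(t) = p(t) - t * dp/dt` with the time derivative by central
#' differences (one-sided at the ends); `t` is measured from the laser
#' firing instant (the first sample).
#'
#' @param channelSamples numeric vector of one channel's time series.
#' @param samplingRate sampling rate in Hz.
#' @return Numeric vector of the same length.
#' @export
rampTerm <- function(channelSamples, samplingRate) {
  x <- as.numeric(channelSamples)
  n <- length(x)
  if (n < 3) stop("at least 3 samples are required")
  fs <- samplingRate
  dp <- numeric(n)
  dp[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  dp[1] <- (x[2] - x[1]) * fs
  dp[n] <- (x[n] - x[n - 1]) * fs
  tt <- (seq_len(n) - 1) / fs
  x - tt * dp
}

.rampPlane <- function(X, fs) {
  ns <- ncol(X)
  dP <- matrix(0, nrow(X), ns)
  dP[, 2:(ns - 1)] <- (X[, 3:ns] - X[, 1:(ns - 2)]) * fs / 2
  dP[, 1] <- (X[, 2] - X[, 1]) * fs
  dP[, ns] <- (X[, ns] - X[, ns - 1]) * fs
  tt <- (seq_len(ns) - 1) / fs
  X - dP * matrix(tt, nrow(X), ns, byrow = TRUE)
}

#' Back-project one RF plane onto a voxel grid
#'
#' @param plane a preprocessed [rfPlane()].
#' @param geom the [buildArray()] geometry at the plane's pose.
#' @param plan the [acquisitionPlan()].
#' @param grid the reconstruction [voxelGrid()].
#' @param directivity a [directivityModel()], or `NULL` to weigh by solid
#'   angle only.
#' @param interp temporal interpolation at `t = d / vs`: `"linear"`
#'   (default) or `"nearest"`.
#' @return A `ReconVolume` of kind `"pressure"`; `info(vol)$uncovered` counts
#'   voxels beyond every element's time window (they contribute nothing).
#' @examples
#' geom <- buildArray(8)
#' plan <- acquisitionPlan(nAngles = 1, nSamples = 1400)
#' grid <- voxelGrid(c(-0.4, -0.4, 8.6), 0.1, c(9L, 9L, 9L))
#' pl <- forwardRF(phantomFixture("point_source"), geom, plan)
#' vol <- backprojectPlane(pl, geom, plan, grid)
#' @export
backprojectPlane <- function(plane, geom, plan, grid, directivity = NULL,
                             interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  if (nrow(plane@samples) != geom@nElements)
    stop("channel count must equal the element count")
  useDir <- !is.null(directivity) && directivity@enabled
  B <- .rampPlane(plane@samples, plane@samplingRate)
  res <- backproject_kernel(B, geom@positions, geom@normals, geom@laterals,
                            geom@elementArea, grid@origin, grid@spacing,
                            grid@dim, plane@samplingRate,
                            plan@soundSpeed * 100,
                            if (useDir) deg2rad(directivity@sigmaL) else -1,
                            if (useDir) deg2rad(directivity@sigmaE) else -1,
                            interp == "nearest")
  new("ReconVolume", grid = grid, values = array(res$values, dim = grid@dim),
      kind = "pressure", compensation = "none", directivityUsed = useDir,
      info = list(uncovered = res$uncovered, poseAngle = plane@poseAngle))
}

setMethod("values", "ReconVolume", function(x) x@values)
setMethod("imageGrid", "ReconVolume", function(x) x@grid)
setMethod("show", "ReconVolume", function(object) {
  cat(sprintf("ReconVolume (%s, compensation: %s%s): %d x %d x %d, range [%.3g, %.3g]\n",
              object@kind, object@compensation,
              if (object@directivityUsed) ", directivity" else "",
              dim(object@values)[1], dim(object@values)[2],
              dim(object@values)[3], min(object@values), max(object@values)))
})

#' @rdname backprojectPlane
#' @param x a `ReconVolume`.
#' @export
reconInfo <- function(x) x@info

#' Fluence-compensate a pressure volume and accumulate
#'
#' Divides the back-projected initial pressure by the pose's modelled
#' fluence, voxel by voxel, and adds the result to the running absorption
#' estimate.  Voxels whose fluence falls below `epsilon` times the pose
#' maximum are masked (contribute nothing) rather than amplified, since the
#' division is unstable where the model predicts almost no light.
#'
#' @param pressure a `ReconVolume` of kind `"pressure"`.
#' @param fluence the [fluenceMap()] for the same pose and grid.
#' @param accumulator a `ReconVolume` to accumulate into, or `NULL` to start
#'   at zero.
#' @param epsilon masking threshold as a fraction of the pose's maximum
#'   fluence (default 0.01).
#' @return The updated accumulator (`kind = "absorption"`,
#'   `compensation = "fluence"`); `info(...)$masked` tallies masked voxels.
#' @export
compensateAndAccumulate <- function(pressure, fluence, accumulator = NULL,
                                    epsilon = 0.01) {
  if (!identical(pressure@grid@dim, fluence@grid@dim) ||
      max(abs(pressure@grid@origin - fluence@grid@origin)) > 1e-9 ||
      abs(pressure@grid@spacing - fluence@grid@spacing) > 1e-12)
    stop("pressure and fluence grids do not match")
  psi <- fluence@values
  psimax <- max(psi)
  if (psimax <= 0) {
    contrib <- array(0, dim = pressure@grid@dim)
    nmask <- prod(pressure@grid@dim)
  } else {
    floorv <- epsilon * psimax
    mask <- psi < floorv
    contrib <- pressure@values / pmax(psi, floorv)
    contrib[mask] <- 0
    nmask <- sum(mask)
  }
  prev <- if (is.null(accumulator)) 0 else accumulator@values
  prevmask <- if (is.null(accumulator)) 0 else accumulator@info$masked
  new("ReconVolume", grid = pressure@grid, values = prev + contrib,
      kind = "absorption", compensation = "fluence",
      directivityUsed = pressure@directivityUsed,
      info = list(masked = prevmask + nmask))
}

#' Precompute per-pose fluence maps
#'
#' @param illum pose-0 [buildIlluminator()] geometry.
#' @param optics [opticalProperties()].
#' @param grid reconstruction [voxelGrid()].
#' @param angles pose angles in degrees.
#' @param nPatches quadrature patches.
#' @return A list of [FluenceVolume][fluenceMap] objects named by angle,
#'   reusable across reconstruction variants via `fluenceCache`.
#' @export
computeFluenceCache <- function(illum, optics, grid, angles,
                                nPatches = 200L) {
  out <- lapply(angles, function(a)
    fluenceMap(grid, rotatePose(illum, a), optics, nPatches))
  names(out) <- formatC(angles, format = "f", digits = 6)
  out
}

#' Reconstruct a full tomographic scan
#'
#' Loops over poses: back-projects each plane with solid-angle (and
#' optionally directivity) weighting, then either accumulates the pressure
#' volumes directly or divides each by that pose's fluence map first
#' (compensation).  Because the illumination rotates with the array, the
#' compensated accumulation cannot be factored into a single fluence
#' division after the fact.
#'
#' @param scan an [RFScan][simulateScan] (already preprocessed, or raw with
#'   `preprocess = TRUE`).
#' @param grid reconstruction [voxelGrid()].
#' @param illum,optics fluence model pieces; required when
#'   `compensation = TRUE`.
#' @param directivity [directivityModel()] or `NULL`.
#' @param compensation divide by per-pose fluence maps (default `FALSE`).
#' @param epsilon compensation masking threshold (default 0.01).
#' @param nPatches fluence quadrature patches (default 200).
#' @param fluenceCache optional precomputed [computeFluenceCache()] list.
#' @param preprocess run [preprocessScan()] first (default `FALSE`).
#' @param interp temporal interpolation mode.
#' @param ... passed to [preprocessScan()] when `preprocess = TRUE`.
#' @return A `ReconVolume` tagged `kind = "absorption"` when compensated,
#'   `"pressure"` otherwise.
#' @export
reconstructScan <- function(scan, grid, illum = NULL, optics = NULL,
                            directivity = NULL, compensation = FALSE,
                            epsilon = 0.01, nPatches = 200L,
                            fluenceCache = NULL, preprocess = FALSE,
                            interp = "linear", ...) {
  if (preprocess) scan <- preprocessScan(scan, ...)$scan
  if (compensation && (is.null(optics)) && is.null(fluenceCache))
    stop("compensation requires optics (and an illuminator) or a fluence cache")
  geom0 <- rotatePose(scan@geometry, -scan@geometry@poseAngle)
  illum0 <- if (!is.null(illum)) rotatePose(illum, -illum@poseAngle)
            else rotatePose(scan@illuminator, -scan@illuminator@poseAngle)
  acc <- NULL
  accP <- array(0, dim = grid@dim)
  uncovered <- 0
  useDir <- !is.null(directivity) && directivity@enabled
  for (pl in scan@planes) {
    gk <- rotatePose(geom0, pl@poseAngle)
    vol <- backprojectPlane(pl, gk, scan@plan, grid, directivity, interp)
    uncovered <- uncovered + vol@info$uncovered
    if (compensation) {
      key <- formatC(pl@poseAngle, format = "f", digits = 6)
      fl <- if (!is.null(fluenceCache) && !is.null(fluenceCache[[key]]))
        fluenceCache[[key]]
      else fluenceMap(grid, rotatePose(illum0, pl@poseAngle), optics,
                      nPatches)
      acc <- compensateAndAccumulate(vol, fl, acc, epsilon)
    } else {
      accP <- accP + vol@values
    }
  }
  if (compensation) {
    acc@info$uncovered <- uncovered
    acc@info$nPoses <- length(scan@planes)
    acc
  } else {
    new("ReconVolume", grid = grid, values = accP, kind = "pressure",
        compensation = "none", directivityUsed = useDir,
        info = list(uncovered = uncovered, masked = 0,
                    nPoses = length(scan@planes)))
  }
}
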