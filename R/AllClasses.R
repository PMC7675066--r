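## S4 containers for the scanner geometry, acquisitions and volumes.
## Lengths are in cm, angles in degrees at every interface (radians are used
## only inside numerical kernels), frequencies in Hz, sound speed in m/s.

.rigid_tol <- 1e-9

#' @rdname voxelGrid
#' @export
setClass("VoxelGrid",
  representation(origin = "numeric", spacing = "numeric", dim = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@origin) != 3) msg <- c(msg, "origin must be length 3")
    if (length(object@spacing) != 1 || object@spacing <= 0)
      msg <- c(msg, "spacing must be a single positive number")
    if (length(object@dim) != 3 || any(object@dim < 1L))
      msg <- c(msg, "dim must be three counts >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname buildArray
#' @export
setClass("ArrayGeometry",
  representation(nElements = "integer", arcLength = "numeric",
    arcRadius = "numeric", positions = "matrix", normals = "matrix",
    laterals = "matrix", elementArea = "numeric", poseAngle = "numeric"),
  validity = function(object) {
    msg <- NULL
    n <- object@nElements
    if (nrow(object@positions) != n) msg <- c(msg, "positions must be n x 3")
    r <- sqrt(rowSums(object@positions^2))
    if (any(abs(r - object@arcRadius) > 1e-8))
      msg <- c(msg, "elements must lie on the dome sphere of the arc radius")
    nrm <- sqrt(rowSums(object@normals^2))
    if (any(abs(nrm - 1) > 1e-8)) msg <- c(msg, "normals must be unit length")
    ## concave array: normals point toward the dome centre
    if (any(rowSums(object@normals * object@positions) > -object@arcRadius + 1e-6))
      msg <- c(msg, "normals must point toward the dome interior")
    if (n > 1) {
      d <- sqrt(rowSums((object@positions[-1, , drop = FALSE] -
                         object@positions[-n, , drop = FALSE])^2))
      if (diff(range(d)) > 1e-8)
        msg <- c(msg, "consecutive element spacing must be constant")
    }
    if (object@elementArea <= 0) msg <- c(msg, "elementArea must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname acquisitionPlan
#' @export
setClass("AcquisitionPlan",
  representation(nAngles = "integer", angularStep = "numeric",
    samplingRate = "numeric", nSamples = "integer", soundSpeed = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@nAngles < 1L) msg <- c(msg, "nAngles must be >= 1")
    if (object@nAngles * object@angularStep > 360 + 1e-9)
      msg <- c(msg, "nAngles * angularStep must not exceed 360 degrees")
    if (object@samplingRate <= 0 || object@soundSpeed <= 0 || object@nSamples < 2L)
      msg <- c(msg, "samplingRate, soundSpeed and nSamples must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname buildIlluminator
#' @export
setClass("IlluminatorGeometry",
  representation(domeRadius = "numeric", windowArcLength = "numeric",
    windowCenterPolar = "numeric", windowAzimuth = "numeric",
    wideDivergence = "numeric", narrowDivergence = "numeric",
    sourcePoint = "numeric", fanAxis = "numeric", poseAngle = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@domeRadius <= 0) msg <- c(msg, "domeRadius must be positive")
    if (object@windowArcLength <= 0 ||
        object@windowArcLength >= pi * object@domeRadius)
      msg <- c(msg, "windowArcLength must be positive and fit on the dome")
    if (object@wideDivergence <= 0 || object@wideDivergence >= 180)
      msg <- c(msg, "wideDivergence must be in (0, 180) degrees")
    if (object@narrowDivergence <= 0 || object@narrowDivergence >= 180)
      msg <- c(msg, "narrowDivergence must be in (0, 180) degrees")
    if (abs(sqrt(sum(object@fanAxis^2)) - 1) > 1e-8)
      msg <- c(msg, "fanAxis must be a unit vector")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname opticalProperties
#' @export
setClass("OpticalProperties",
  representation(muA0 = "numeric", muS = "numeric", g = "numeric",
    muSPrime = "numeric", D = "numeric", muEff = "numeric",
    diffusionOK = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@muA0 < 0 || object@muS < 0) msg <- c(msg, "coefficients must be >= 0")
    if (object@g < 0 || object@g >= 1) msg <- c(msg, "g must be in [0, 1)")
    if ((object@muEff == 0) != (object@muA0 == 0))
      msg <- c(msg, "muEff must be zero iff muA0 is zero")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname fluenceMap
#' @export
setClass("FluenceVolume",
  representation(grid = "VoxelGrid", poseAngle = "numeric", values = "array"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@values), as.integer(object@grid@dim)))
      msg <- c(msg, "values must match the grid dimensions")
    if (any(!is.finite(object@values)) || any(object@values < 0))
      msg <- c(msg, "fluence values must be finite and non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname phantomModel
#' @export
setClass("PhantomModel",
  representation(wires = "data.frame", backgroundAbsorption = "numeric"),
  validity = function(object) {
    msg <- NULL
    need <- c("x0", "y0", "z0", "x1", "y1", "z1", "radius", "absorption")
    if (!all(need %in% names(object@wires)))
      msg <- c(msg, paste("wires needs columns:", paste(need, collapse = ", ")))
    else if (nrow(object@wires) > 0 && any(object@wires$radius <= 0))
      msg <- c(msg, "wire radii must be positive")
    if (object@backgroundAbsorption < 0)
      msg <- c(msg, "backgroundAbsorption must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname noiseModel
#' @export
setClass("NoiseModel",
  representation(bandCount = "integer", bandRank = "integer",
    bandAmplitude = "numeric", whiteSigma = "numeric",
    energyJitter = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@bandCount < 0L || object@bandRank < 1L)
      msg <- c(msg, "bandCount must be >= 0 and bandRank >= 1")
    if (object@bandAmplitude < 0 || object@whiteSigma < 0)
      msg <- c(msg, "amplitudes must be >= 0")
    if (object@energyJitter < 0 || object@energyJitter >= 1)
      msg <- c(msg, "energyJitter must be a fraction in [0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname rfPlane
#' @export
setClass("RFPlane",
  representation(poseAngle = "numeric", samples = "matrix",
    pulseEnergy = "numeric", samplingRate = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(!is.finite(object@samples))) msg <- c(msg, "samples must be finite")
    if (object@pulseEnergy <= 0) msg <- c(msg, "pulseEnergy must be positive")
    if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname simulateScan
#' @export
setClass("RFScan",
  representation(planes = "list", plan = "AcquisitionPlan",
    geometry = "ArrayGeometry", illuminator = "IlluminatorGeometry"),
  validity = function(object) {
    ok <- all(vapply(object@planes, is, logical(1), class2 = "RFPlane"))
    bad <- any(vapply(object@planes, function(p)
      nrow(p@samples) != object@geometry@nElements, logical(1)))
    msg <- NULL
    if (!ok) msg <- c(msg, "planes must be RFPlane objects")
    else if (bad) msg <- c(msg, "channel count must equal the element count")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname directivityModel
#' @export
setClass("DirectivityModel",
  representation(sigmaL = "numeric", sigmaE = "numeric", enabled = "logical"),
  validity = function(object) {
    if (object@sigmaL <= 0 || object@sigmaE <= 0)
      "sigmaL and sigmaE must be positive (degrees)" else TRUE
  })

#' @rdname backprojectPlane
#' @export
setClass("ReconVolume",
  representation(grid = "VoxelGrid", values = "array", kind = "character",
    compensation = "character", directivityUsed = "logical", info = "list"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@values), as.integer(object@grid@dim)))
      msg <- c(msg, "values must match the grid dimensions")
    if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
    if (!object@kind %in% c("pressure", "absorption"))
      msg <- c(msg, "kind must be 'pressure' or 'absorption'")
    if (!object@compensation %in% c("none", "fluence"))
      msg <- c(msg, "compensation must be 'none' or 'fluence'")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname svdDenoise
#' @export
setClass("DenoiseReport",
  representation(discardedRank = "integer", noiseFraction = "numeric",
    flagged = "logical"),
  validity = function(object) {
    if (any(object@noiseFraction < -1e-12 | object@noiseFraction > 1 + 1e-12))
      "noiseFraction must lie in [0, 1]" else TRUE
  })
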