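## Scanner geometry.
##
## Coordinate frame: origin at the dome centre of curvature, z along the
## rotation axis pointing away from the dome opening (the dome apex sits at
## (0, 0, domeRadius)).  The imaging plane of pose 0 is the x-z plane; a pose
## at angle a is the same rigid body rotated by a about z.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

.rotz <- function(angle_deg) {
  a <- deg2rad(angle_deg %% 360)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Define a voxel grid
#'
#' @param origin centre of the first voxel `(x, y, z)` in cm.
#' @param spacing isotropic voxel spacing in cm (default 0.05 cm = 0.5 mm,
#'   the reconstruction resolution used throughout).
#' @param dim integer vector of three voxel counts.
#' @return A `VoxelGrid` object.
#' @examples
#' g <- voxelGrid(c(-1, -1, 8), 0.1, c(21L, 21L, 21L))
#' head(voxelCenters(g)$x)
#' @export
voxelGrid <- function(origin, spacing = 0.05, dim) {
  new("VoxelGrid", origin = as.numeric(origin), spacing = as.numeric(spacing),
      dim = as.integer(dim))
}

#' @rdname voxelGrid
#' @param grid a `VoxelGrid`.
#' @return `voxelCenters` returns a list with the per-axis centre coordinates
#'   `x`, `y`, `z` (cm); `voxelCenterMatrix` the full `prod(dim) x 3` matrix in
#'   column-major voxel order (x fastest).
#' @export
voxelCenters <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  list(x = grid@origin[1] + (seq_len(grid@dim[1]) - 1) * grid@spacing,
       y = grid@origin[2] + (seq_len(grid@dim[2]) - 1) * grid@spacing,
       z = grid@origin[3] + (seq_len(grid@dim[3]) - 1) * grid@spacing)
}

#' @rdname voxelGrid
#' @export
voxelCenterMatrix <- function(grid) {
  cc <- voxelCenters(grid)
  cbind(x = rep(cc$x, times = grid@dim[2] * grid@dim[3]),
        y = rep(rep(cc$y, each = grid@dim[1]), times = grid@dim[3]),
        z = rep(cc$z, each = grid@dim[1] * grid@dim[2]))
}

#' @rdname voxelGrid
#' @param x a `VoxelGrid`.
#' @export
gridDim <- function(x) x@dim

#' @rdname voxelGrid
#' @export
gridSpacing <- function(x) x@spacing

#' @rdname voxelGrid
#' @export
gridOrigin <- function(x) x@origin

#' Build the arc transducer array
#'
#' Places `nElements` point-like detector elements uniformly along a circular
#' arc of length `arcLength` lying on the dome sphere (radius `arcRadius`) in
#' the x-z plane, symmetric about the arc midpoint at polar angle
#' `arcCenterPolar` measured from the dome apex.  Element normals point toward
#' the dome centre (the array is concave); the lateral direction is the arc
#' tangent toward increasing element index.
#'
#' The elevational extent of one element is not derivable from the arc layout;
#' `elevAperture` fixes it so that the element area entering the solid-angle
#' weights is finite.  Only relative weights matter in the back-projection, so
#' its exact value is uncritical.
#'
#' @param nElements number of elements (default 384).
#' @param arcLength arc length in cm (default 11.5).
#' @param arcRadius dome/arc radius of curvature in cm (default 12).
#' @param arcCenterPolar polar angle (degrees from the apex) of the arc
#'   midpoint; the default places the arc between the apex and the dome rim.
#' @param elevAperture assumed elevational element extent in cm (default 0.5).
#' @return An `ArrayGeometry` at pose 0.
#' @examples
#' arr <- buildArray(384)
#' nElements(arr)
#' @export
buildArray <- function(nElements = 384L, arcLength = 11.5, arcRadius = 12,
                       arcCenterPolar = 27.5, elevAperture = 0.5) {
  nElements <- as.integer(nElements)
  if (nElements < 2L) stop("nElements must be >= 2")
  if (arcLength <= 0 || arcRadius <= 0 || elevAperture <= 0)
    stop("lengths must be positive")
  if (arcLength >= 2 * pi * arcRadius)
    stop("arcLength must be shorter than the full circle")
  span <- arcLength / arcRadius                      # radians
  alpha <- deg2rad(arcCenterPolar) + seq(-span / 2, span / 2,
                                         length.out = nElements)
  pos <- arcRadius * cbind(sin(alpha), 0, cos(alpha))
  nrm <- -pos / arcRadius
  lat <- cbind(cos(alpha), 0, -sin(alpha))           # d(pos)/d(alpha), unit
  pitch <- arcLength / (nElements - 1)
  new("ArrayGeometry", nElements = nElements, arcLength = arcLength,
      arcRadius = arcRadius, positions = pos, normals = nrm, laterals = lat,
      elementArea = pitch * elevAperture, poseAngle = 0)
}

#' @rdname buildArray
#' @param x an `ArrayGeometry`.
#' @export
nElements <- function(x) x@nElements

#' @rdname buildArray
#' @export
elementPositions <- function(x) x@positions

#' @rdname buildArray
#' @export
elementNormals <- function(x) x@normals

#' @rdname buildArray
#' @export
elementLaterals <- function(x) x@laterals

#' @rdname buildArray
#' @export
elementArea <- function(x) x@elementArea

#' Define the acquisition plan
#'
#' @param nAngles number of tomographic poses (default 200).
#' @param angularStep angular spacing between poses in degrees (default 1.8).
#' @param samplingRate DAQ sampling rate in Hz (default 40e6).
#' @param nSamples samples recorded per channel (default 2080).
#' @param soundSpeed assumed constant sound speed in m/s (default 1500).
#' @return An `AcquisitionPlan`.
#' @seealso [requiredSamples()] to size `nSamples` for a given grid.
#' @export
acquisitionPlan <- function(nAngles = 200L, angularStep = 1.8,
                            samplingRate = 40e6, nSamples = 2080L,
                            soundSpeed = 1500) {
  new("AcquisitionPlan", nAngles = as.integer(nAngles),
      angularStep = as.numeric(angularStep), samplingRate = samplingRate,
      nSamples = as.integer(nSamples), soundSpeed = soundSpeed)
}

#' @rdname acquisitionPlan
#' @param geom an [ArrayGeometry][buildArray].
#' @param grid a [voxelGrid()].
#' @param plan an `AcquisitionPlan` supplying rate and sound speed.
#' @param pad extra samples beyond the farthest voxel (pulse support margin).
#' @return `requiredSamples` returns the smallest `nSamples` whose time window
#'   covers every element-to-voxel distance of the grid at any pose.
#' @export
requiredSamples <- function(geom, grid, plan, pad = 32L) {
  vx <- voxelCenterMatrix(grid)
  ## distances are rotation-invariant in the radial/axial decomposition:
  ## max over poses is attained in-plane, bounded by rho_e + rho_v radially
  ep <- geom@positions
  rho_e <- sqrt(ep[, 1]^2 + ep[, 2]^2)
  rho_v <- sqrt(vx[, 1]^2 + vx[, 2]^2)
  dmax <- 0
  for (e in seq_len(nrow(ep))) {
    d2 <- (rho_e[e] + rho_v)^2 + (ep[e, 3] - vx[, 3])^2
    dmax <- max(dmax, max(d2))
  }
  dmax <- sqrt(dmax)
  per_sample <- (plan@soundSpeed * 100) / plan@samplingRate   # cm
  as.integer(ceiling(dmax / per_sample)) + as.integer(pad)
}

#' Build the fan-beam illuminator
#'
#' The fan-shaped diffuse beam leaves a virtual source point inside the dome
#' and illuminates a narrow band `B` of the dome surface (the optical window,
#' an arc parallel to the transducer arc).  The wide divergence spans the
#' window's full arc length; the narrow divergence makes the band a quasi-1D
#' strip.  The source point is placed on the inward radial line through the
#' window centre at the distance for which the wide divergence exactly covers
#' the window arc.
#'
#' @param domeRadius dome radius in cm (default 12).
#' @param windowArcLength illuminated window arc length in cm (default 11.5).
#' @param windowCenterPolar polar angle of the window-arc midpoint, degrees
#'   from the apex (default 27.5, parallel to the transducer arc).
#' @param windowAzimuth azimuthal offset of the window from the imaging plane
#'   in degrees (default 15).
#' @param wideDivergence fan divergence along the window, degrees (default 90).
#' @param narrowDivergence fan divergence across the window, degrees
#'   (default 0.24).
#' @return An `IlluminatorGeometry` at pose 0.
#' @examples
#' ill <- buildIlluminator()
#' poseAngle(ill)
#' @export
buildIlluminator <- function(domeRadius = 12, windowArcLength = 11.5,
                             windowCenterPolar = 27.5, windowAzimuth = 15,
                             wideDivergence = 90, narrowDivergence = 0.24) {
  ac <- deg2rad(windowCenterPolar)
  az <- deg2rad(windowAzimuth)
  wc <- domeRadius * c(sin(ac) * cos(az), sin(ac) * sin(az), cos(ac))
  standoff <- (windowArcLength / 2) / tan(deg2rad(wideDivergence / 2))
  src <- wc * (1 - standoff / domeRadius)
  axis <- wc / sqrt(sum(wc^2))
  new("IlluminatorGeometry", domeRadius = domeRadius,
      windowArcLength = windowArcLength,
      windowCenterPolar = windowCenterPolar, windowAzimuth = windowAzimuth,
      wideDivergence = wideDivergence, narrowDivergence = narrowDivergence,
      sourcePoint = src, fanAxis = axis, poseAngle = 0)
}

#' @rdname buildIlluminator
#' @param x an `IlluminatorGeometry`.
#' @export
sourcePoint <- function(x) x@sourcePoint

#' Window-band quadrature patches
#'
#' Lays out `nPatches` quadrature patches on the illuminated dome band `B`,
#' uniform in the two fan divergence angles.  A patch centre is the
#' intersection of the fan ray at angle `(theta, phi)` with the dome sphere;
#' its quadrature weight is the angle element `dtheta * dphi` it represents,
#' matching the fluence surface integral's parameterization over the two
#' beam angles.  Because the band is a quasi-1D strip (narrow divergence
#' 0.24 degrees), the transverse subdivision defaults to a single patch
#' unless `nPhi` is given.
#'
#' @param illum an [IlluminatorGeometry][buildIlluminator].
#' @param nPatches total number of patches (default 200).
#' @param nPhi number of transverse subdivisions (default 1).
#' @return A list with `centers` (nPatches x 3, cm, on the dome sphere) and
#'   `areas` (nPatches, the `dtheta * dphi` quadrature weights in rad^2), at
#'   the illuminator's current pose.
#' @export
windowPatches <- function(illum, nPatches = 200L, nPhi = 1L) {
  nPatches <- as.integer(nPatches); nPhi <- as.integer(nPhi)
  if (nPatches < 1L) stop("nPatches must be >= 1")
  if (nPhi < 1L || nPatches %% nPhi != 0L)
    stop("nPhi must divide nPatches")
  nTheta <- nPatches %/% nPhi
  R <- illum@domeRadius
  ac <- deg2rad(illum@windowCenterPolar)
  az0 <- deg2rad(illum@windowAzimuth)
  ## pose-0 frame: fan axis, window tangent (wide axis) and transverse axis
  axis <- c(sin(ac) * cos(az0), sin(ac) * sin(az0), cos(ac))
  tangent <- c(cos(ac) * cos(az0), cos(ac) * sin(az0), -sin(ac))
  transverse <- c(axis[2] * tangent[3] - axis[3] * tangent[2],
                  axis[3] * tangent[1] - axis[1] * tangent[3],
                  axis[1] * tangent[2] - axis[2] * tangent[1])
  src <- as.numeric(.rotz(-illum@poseAngle) %*% illum@sourcePoint)
  wide <- deg2rad(illum@wideDivergence)
  narrow <- deg2rad(illum@narrowDivergence)
  thetas <- (seq_len(nTheta) - 0.5) / nTheta * wide - wide / 2
  phis <- (seq_len(nPhi) - 0.5) / nPhi * narrow - narrow / 2
  w0 <- (wide / nTheta) * (narrow / nPhi)
  centers <- matrix(0, nPatches, 3)
  k <- 0L
  for (it in seq_len(nTheta)) for (ip in seq_len(nPhi)) {
    k <- k + 1L
    u <- cos(thetas[it]) * cos(phis[ip]) * axis +
         sin(thetas[it]) * cos(phis[ip]) * tangent +
         sin(phis[ip]) * transverse
    ## ray-sphere intersection from the source point
    pu <- sum(src * u)
    s <- -pu + sqrt(pu^2 + R^2 - sum(src^2))
    centers[k, ] <- src + s * u
  }
  Rz <- .rotz(illum@poseAngle)
  list(centers = t(Rz %*% t(centers)), areas = rep(w0, nPatches))
}

#' Lateral/elevational angles between an element and a voxel
#'
#' Decomposes the direction from a transducer element to a sample point into
#' the lateral (in-plane) angle `thetaL` and the elevational (out-of-plane)
#' angle `thetaE` relative to the element normal, the two angles the Gaussian
#' directivity model depends on.
#'
#' @param elementPos element position (cm).
#' @param elementNormal unit element normal (toward the dome interior).
#' @param elementLateral unit arc tangent at the element.
#' @param voxel sample point (cm).
#' @return A list with `thetaL`, `thetaE` (degrees, in (-90, 90] for points in
#'   the forward half-space) and `distance` (cm).
#' @examples
#' arr <- buildArray(3)
#' p <- elementPositions(arr)[2, ] + elementNormals(arr)[2, ] * 5
#' elementAngles(elementPositions(arr)[2, ], elementNormals(arr)[2, ],
#'               elementLaterals(arr)[2, ], p)
#' @export
elementAngles <- function(elementPos, elementNormal, elementLateral, voxel) {
  v <- voxel - elementPos
  d <- sqrt(sum(v^2))
  if (d == 0) stop("voxel coincides with the element position")
  u <- v / d
  elev <- c(elementNormal[2] * elementLateral[3] - elementNormal[3] * elementLateral[2],
            elementNormal[3] * elementLateral[1] - elementNormal[1] * elementLateral[3],
            elementNormal[1] * elementLateral[2] - elementNormal[2] * elementLateral[1])
  a <- sum(u * elementNormal)
  l <- sum(u * elementLateral)
  e <- sum(u * elev)
  list(thetaL = rad2deg(atan2(l, a)), thetaE = rad2deg(atan2(e, a)),
       distance = d)
}

#' Solid-angle weight of one element seen from a voxel
#'
#' The solid angle subtended by a detector surface element of area `A` at a
#' sample point: `A * cos(gamma) / d^2`, where `gamma` is the total
#' inclination between the element normal and the element-to-voxel direction.
#' Back-facing voxels get weight 0.
#'
#' @param elementPos,elementNormal element position (cm) and unit normal.
#' @param elementArea element area in cm^2.
#' @param voxel sample point (cm).
#' @return Solid angle in steradians (>= 0).
#' @export
solidAngleWeight <- function(elementPos, elementNormal, elementArea, voxel) {
  v <- voxel - elementPos
  d2 <- sum(v^2)
  if (d2 == 0) stop("voxel coincides with the element position")
  cosg <- sum(v * elementNormal) / sqrt(d2)
  elementArea * max(cosg, 0) / d2
}

#' @rdname rotatePose
setMethod("rotatePose", "ArrayGeometry", function(x, angle) {
  Rz <- .rotz(angle)
  new("ArrayGeometry", nElements = x@nElements, arcLength = x@arcLength,
      arcRadius = x@arcRadius,
      positions = t(Rz %*% t(x@positions)),
      normals = t(Rz %*% t(x@normals)),
      laterals = t(Rz %*% t(x@laterals)),
      elementArea = x@elementArea,
      poseAngle = (x@poseAngle + angle) %% 360)
})

#' @rdname rotatePose
setMethod("rotatePose", "IlluminatorGeometry", function(x, angle) {
  Rz <- .rotz(angle)
  x@sourcePoint <- as.numeric(Rz %*% x@sourcePoint)
  x@fanAxis <- as.numeric(Rz %*% x@fanAxis)
  x@poseAngle <- (x@poseAngle + angle) %% 360
  x
})

#' @rdname rotatePose
#' @param geom an [ArrayGeometry][buildArray].
#' @param illum an [IlluminatorGeometry][buildIlluminator].
#' @return `rotateAcquisition` returns `list(geometry=, illuminator=)`, both
#'   rotated by the same rigid transform.
#' @export
rotateAcquisition <- function(geom, illum, angle) {
  list(geometry = rotatePose(geom, angle),
       illuminator = rotatePose(illum, angle))
}

setMethod("poseAngle", "ArrayGeometry", function(x) x@poseAngle)
setMethod("poseAngle", "IlluminatorGeometry", function(x) x@poseAngle)

setMethod("show", "ArrayGeometry", function(object) {
  cat(sprintf("ArrayGeometry: %d elements, %.1f cm arc, radius %.1f cm, pose %.1f deg\n",
              object@nElements, object@arcLength, object@arcRadius,
              object@poseAngle))
})

setMethod("show", "IlluminatorGeometry", function(object) {
  cat(sprintf("IlluminatorGeometry: %.0f x %.2f deg fan, %.1f cm window, pose %.1f deg\n",
              object@wideDivergence, object@narrowDivergence,
              object@windowArcLength, object@poseAngle))
})

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %d x %d x %d voxels @ %.2f mm\n",
              object@dim[1], object@dim[2], object@dim[3],
              object@spacing * 10))
})
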