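#' Accessors for fanpat containers
#'
#' Small accessor generics so user code never touches slots directly:
#' `values()` returns the voxel array of a [FluenceVolume][fluenceMap] or
#' [ReconVolume][backprojectPlane], `imageGrid()` its [voxelGrid()],
#' `poseAngle()` the tomographic angle (degrees) of a pose-bound object,
#' `rfSamples()` the channels-by-time matrix of an [RFPlane][rfPlane],
#' `pulseEnergy()` its per-pulse energy (mJ), and `planes()` the list of
#' [RFPlane][rfPlane] objects of an [RFScan][simulateScan].
#'
#' @param x a fanpat object.
#' @param value replacement value.
#' @return The slot content; replacement forms return the modified object.
#' @examples
#' g <- voxelGrid(c(0, 0, 0), 0.1, c(4L, 4L, 4L))
#' gridDim(g)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("imageGrid", function(x) standardGeneric("imageGrid"))
#' @rdname accessors
#' @export
setGeneric("poseAngle", function(x) standardGeneric("poseAngle"))
#' @rdname accessors
#' @export
setGeneric("rfSamples", function(x) standardGeneric("rfSamples"))
#' @rdname accessors
#' @export
setGeneric("rfSamples<-", function(x, value) standardGeneric("rfSamples<-"))
#' @rdname accessors
#' @export
setGeneric("pulseEnergy", function(x) standardGeneric("pulseEnergy"))
#' @rdname accessors
#' @export
setGeneric("planes", function(x) standardGeneric("planes"))

#' Rotate a pose-bound object about the dome axis
#'
#' The scanner acquires tomographic planes by rigidly rotating the dome (and
#' with it the transducer arc and the illuminator, which are fixed relative to
#' one another) about its symmetry axis.  `rotatePose` applies that rigid
#' rotation; pairwise distances are preserved exactly.
#'
#' @param x an [ArrayGeometry][buildArray] or
#'   [IlluminatorGeometry][buildIlluminator].
#' @param angle rotation angle in degrees (taken modulo 360).
#' @return An object of the same class at the rotated pose.
#' @examples
#' arr <- buildArray(8)
#' r <- rotatePose(arr, 90)
#' poseAngle(r)
#' @export
setGeneric("rotatePose", function(x, angle) standardGeneric("rotatePose"))
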