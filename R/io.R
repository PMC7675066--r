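## On-disk formats: volumes as NIfTI with a JSON sidecar for grid metadata,
## RF scans as a 3D NIfTI stack (channel x sample x pose) plus a JSON sidecar
## holding pose angles, pulse energies, sampling metadata and the geometry.

.sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write / read a reconstruction or fluence volume
#'
#' @param vol a `ReconVolume` or `FluenceVolume`.
#' @param path output path ending in `.nii` or `.nii.gz`; a JSON sidecar
#'   with the grid, kind and options is written next to it.
#' @param extra named list merged into the sidecar (e.g. config hash).
#' @return `writeVolume` returns `path` invisibly; `readVolume` the restored
#'   object.
#' @export
writeVolume <- function(vol, path, extra = list()) {
  g <- vol@grid
  img <- RNifti::asNifti(vol@values,
                         pixdim = rep(g@spacing * 10, 3)) # cm -> mm
  RNifti::writeNifti(img, path)
  meta <- list(origin = g@origin, spacing = g@spacing, dim = as.integer(g@dim))
  if (is(vol, "ReconVolume"))
    meta <- c(meta, list(class = "ReconVolume", kind = vol@kind,
                         compensation = vol@compensation,
                         directivity = vol@directivityUsed, info = vol@info))
  else
    meta <- c(meta, list(class = "FluenceVolume", poseAngle = vol@poseAngle))
  jsonlite::write_json(c(meta, extra), .sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  vals <- array(as.numeric(RNifti::readNifti(path)),
                dim = as.integer(meta$dim))
  grid <- voxelGrid(meta$origin, meta$spacing, as.integer(meta$dim))
  if (identical(meta$class, "FluenceVolume"))
    new("FluenceVolume", grid = grid, poseAngle = meta$poseAngle,
        values = vals)
  else
    new("ReconVolume", grid = grid, values = vals, kind = meta$kind,
        compensation = meta$compensation,
        directivityUsed = isTRUE(meta$directivity),
        info = if (is.null(meta$info)) list() else as.list(meta$info))
}

#' Write / read an RF scan container
#'
#' The channel data of all poses are stacked into one 3D NIfTI volume
#' (channels x samples x poses); acquisition metadata and the full geometry
#' travel in a JSON sidecar so the scan is self-describing.
#'
#' @param scan an [RFScan][simulateScan].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param extra named list merged into the sidecar.
#' @return `writeRFScan` returns `path` invisibly; `readRFScan` the restored
#'   `RFScan`.
#' @export
writeRFScan <- function(scan, path, extra = list()) {
  np <- length(scan@planes)
  nch <- scan@geometry@nElements
  ns <- scan@plan@nSamples
  arr <- array(0, dim = c(nch, ns, np))
  for (i in seq_len(np)) arr[, , i] <- scan@planes[[i]]@samples
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  g <- scan@geometry; p <- scan@plan; il <- scan@illuminator
  meta <- list(
    class = "RFScan",
    poseAngles = vapply(scan@planes, poseAngle, numeric(1)),
    pulseEnergies = vapply(scan@planes, pulseEnergy, numeric(1)),
    plan = list(nAngles = p@nAngles, angularStep = p@angularStep,
                samplingRate = p@samplingRate, nSamples = p@nSamples,
                soundSpeed = p@soundSpeed),
    geometry = list(nElements = g@nElements, arcLength = g@arcLength,
                    arcRadius = g@arcRadius, elementArea = g@elementArea,
                    poseAngle = g@poseAngle,
                    positions = g@positions, normals = g@normals,
                    laterals = g@laterals),
    illuminator = list(domeRadius = il@domeRadius,
                       windowArcLength = il@windowArcLength,
                       windowCenterPolar = il@windowCenterPolar,
                       windowAzimuth = il@windowAzimuth,
                       wideDivergence = il@wideDivergence,
                       narrowDivergence = il@narrowDivergence,
                       poseAngle = il@poseAngle))
  jsonlite::write_json(c(meta, extra), .sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRFScan
#' @export
readRFScan <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  arr <- as.numeric(RNifti::readNifti(path))
  p <- meta$plan
  plan <- acquisitionPlan(p$nAngles, p$angularStep, p$samplingRate,
                          p$nSamples, p$soundSpeed)
  gm <- meta$geometry
  geom <- new("ArrayGeometry", nElements = as.integer(gm$nElements),
              arcLength = gm$arcLength, arcRadius = gm$arcRadius,
              positions = matrix(unlist(gm$positions), ncol = 3),
              normals = matrix(unlist(gm$normals), ncol = 3),
              laterals = matrix(unlist(gm$laterals), ncol = 3),
              elementArea = gm$elementArea, poseAngle = gm$poseAngle)
  il <- meta$illuminator
  illum <- buildIlluminator(il$domeRadius, il$windowArcLength,
                            il$windowCenterPolar, il$windowAzimuth,
                            il$wideDivergence, il$narrowDivergence)
  if (il$poseAngle != 0) illum <- rotatePose(illum, il$poseAngle)
  np <- length(meta$poseAngles)
  arr <- array(arr, dim = c(gm$nElements, p$nSamples, np))
  pls <- lapply(seq_len(np), function(i)
    rfPlane(arr[, , i], poseAngle = meta$poseAngles[i],
            pulseEnergy = meta$pulseEnergies[i],
            samplingRate = p$samplingRate))
  new("RFScan", planes = pls, plan = plan, geometry = geom,
      illuminator = illum)
}
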