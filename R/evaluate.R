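## Image-quality metrics: profile SNR/FWHM, RMSE, relative image error and
## depth-resolved error shells, plus the four-variant comparison experiment.

.vol_values <- function(x) if (is(x, "ReconVolume")) x@values else as.array(x)

.normalize_volume <- function(v, policy = c("unit-max", "unit-norm", "none")) {
  policy <- match.arg(policy)
  switch(policy,
    "unit-max" = { m <- max(abs(v)); if (m > 0) v / m else v },
    "unit-norm" = { m <- sqrt(sum(v^2)); if (m > 0) v / m else v },
    "none" = v)
}

#' SNR and FWHM of an amplitude profile
#'
#' The peak region is the contiguous run of samples around the global maximum
#' whose amplitude exceeds half that maximum; its width times the sample
#' spacing is the FWHM.  SNR is the mean amplitude over the peak region
#' divided by the standard deviation of the amplitude over the whole image,
#' reported in dB as `20 log10` of the ratio (amplitude quantities).
#'
#' @param profile sampled amplitude line (numeric vector).
#' @param imageValues all image amplitudes the noise level is taken from.
#' @param spacing sample spacing along the profile, mm.
#' @return A list with `snr_db`, `snr`, `fwhm` (mm) and `peakRegion`
#'   (first/last index of the half-maximum run).
#' @export
snrFwhm <- function(profile, imageValues, spacing) {
  profile <- as.numeric(profile)
  m <- max(profile)
  if (!is.finite(m) || m <= 0 || all(profile == profile[1]))
    stop("profile has no positive peak")
  imax <- which.max(profile)
  above <- profile > 0.5 * m
  i0 <- imax
  while (i0 > 1 && above[i0 - 1]) i0 <- i0 - 1
  i1 <- imax
  while (i1 < length(profile) && above[i1 + 1]) i1 <- i1 + 1
  noise <- sd(as.numeric(.vol_values(imageValues)))
  if (!is.finite(noise) || noise == 0) stop("image amplitude spread is zero")
  snr <- mean(profile[i0:i1]) / noise
  list(snr_db = 20 * log10(snr), snr = snr,
       fwhm = (i1 - i0 + 1) * spacing, peakRegion = c(i0, i1))
}

#' Root-mean-squared error between two images
#'
#' @param a,b arrays (or `ReconVolume`s) of identical shape.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  a <- .vol_values(a); b <- .vol_values(b)
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  sqrt(mean((a - b)^2))
}

#' Relative image error against a model volume
#'
#' The two-norm of the voxelwise difference between the reconstruction and
#' the ground-truth model, divided by the two-norm of the model.  Because
#' reconstructions are in arbitrary units while the model is (near-)binary,
#' both volumes are normalized first; the default scales each to unit
#' maximum.
#'
#' @param a reconstructed volume (array or `ReconVolume`).
#' @param m model volume of the same shape.
#' @param normalize `"unit-max"` (default), `"unit-norm"` or `"none"`.
#' @return The scalar relative error (0 for a perfect reconstruction, 1 for
#'   an all-zero one).
#' @export
imageError <- function(a, m, normalize = "unit-max") {
  a <- .vol_values(a); m <- .vol_values(m)
  if (!identical(dim(a), dim(m))) stop("images must have the same shape")
  if (all(m == 0)) stop("model volume is all zero")
  a <- .normalize_volume(a, normalize)
  m <- .normalize_volume(m, normalize)
  sqrt(sum((a - m)^2)) / sqrt(sum(m^2))
}

#' Depth-resolved image error
#'
#' Evaluates the relative image error restricted to concentric spherical
#' shells of equal width in depth below the dome surface (distance
#' `domeRadius - |r - center|`), resolving how reconstruction fidelity
#' degrades with imaging depth.
#'
#' @inheritParams imageError
#' @param grid the [voxelGrid()] both volumes live on.
#' @param center dome centre of curvature (default the origin).
#' @param nShells number of shells (default 50).
#' @param domeRadius dome radius in cm (default 12).
#' @return A list of class `"DepthErrorCurve"` with `shellEdges` (depth
#'   edges, cm), `depth` (shell midpoints), `error` (per-shell relative
#'   error, `NA` for shells without model content), `num2`/`den2` (per-shell
#'   squared numerator/denominator sums, which recombine to the global
#'   error), and `count` (voxels per shell).
#' @export
depthError <- function(a, m, grid, center = c(0, 0, 0), nShells = 50L,
                       domeRadius = 12, normalize = "unit-max") {
  a <- .vol_values(a); m <- .vol_values(m)
  if (!identical(dim(a), dim(m))) stop("images must have the same shape")
  a <- .normalize_volume(a, normalize)
  m <- .normalize_volume(m, normalize)
  vox <- voxelCenterMatrix(grid)
  depth <- domeRadius - sqrt((vox[, 1] - center[1])^2 +
                             (vox[, 2] - center[2])^2 +
                             (vox[, 3] - center[3])^2)
  edges <- seq(min(depth), max(depth), length.out = nShells + 1)
  ## assign voxels to shells; the deepest edge is inclusive
  bin <- pmin(pmax(findInterval(depth, edges, rightmost.closed = TRUE), 1L),
              nShells)
  d2 <- as.numeric((a - m)^2)
  m2 <- as.numeric(m^2)
  num2 <- vapply(seq_len(nShells), function(s) sum(d2[bin == s]), numeric(1))
  den2 <- vapply(seq_len(nShells), function(s) sum(m2[bin == s]), numeric(1))
  cnt <- tabulate(bin, nShells)
  err <- ifelse(den2 > 0, sqrt(num2) / sqrt(den2), NA_real_)
  structure(list(shellEdges = edges,
                 depth = (edges[-1] + edges[-(nShells + 1)]) / 2,
                 error = err, num2 = num2, den2 = den2, count = cnt),
            class = "DepthErrorCurve")
}

#' @rdname depthError
#' @param x a `DepthErrorCurve`.
#' @param ... ignored.
#' @export
print.DepthErrorCurve <- function(x, ...) {
  cat(sprintf("DepthErrorCurve: %d shells, depth %.2f..%.2f cm, %d populated\n",
              length(x$error), min(x$shellEdges), max(x$shellEdges),
              sum(!is.na(x$error))))
  invisible(x)
}

#' Extract an amplitude profile along a line
#'
#' Samples a volume along the segment `p0 -> p1` by trilinear interpolation.
#'
#' @param vol a `ReconVolume` (or array with `grid`).
#' @param p0,p1 segment endpoints, cm.
#' @param n number of samples (default 101).
#' @param grid required when `vol` is a plain array.
#' @return A list with `values`, `spacing` (mm between samples) and `t`
#'   (positions along the line, cm).
#' @export
extractProfile <- function(vol, p0, p1, n = 101L, grid = NULL) {
  if (is(vol, "ReconVolume")) { grid <- vol@grid; vals <- vol@values }
  else vals <- as.array(vol)
  if (is.null(grid)) stop("grid is required for a plain array")
  tt <- seq(0, 1, length.out = n)
  pts <- cbind(p0[1] + tt * (p1[1] - p0[1]), p0[2] + tt * (p1[2] - p0[2]),
               p0[3] + tt * (p1[3] - p0[3]))
  len <- sqrt(sum((p1 - p0)^2))
  list(values = interpVolume(vals, grid, pts),
       spacing = len / (n - 1) * 10, t = tt * len)
}

#' Compare the four reconstruction variants
#'
#' Reconstructs a scan with and without transducer directivity and with and
#' without illumination (fluence) compensation, and scores each variant
#' against the ground-truth model: relative image error, depth-resolved
#' error shells, and (when a profile line is given) SNR and FWHM across an
#' inclusion.
#'
#' @param scan a preprocessed [RFScan][simulateScan].
#' @param model the ground-truth model volume ([voxelizePhantom()]).
#' @param grid reconstruction [voxelGrid()].
#' @param illum,optics fluence model pieces for the compensated variants.
#' @param directivity [directivityModel()] used by the directivity variants.
#' @param profile optional `list(p0=, p1=, n=)` line for SNR/FWHM.
#' @param nShells depth shells (default 50).
#' @param nPatches fluence quadrature patches (default 200).
#' @param epsilon compensation masking threshold.
#' @param domeRadius dome radius for depth binning.
#' @return A list with `variants` (per-variant list of `recon`, `error`,
#'   `depth`, optional `snr`) and `table` (a data.frame in Table form:
#'   directivity x compensation, with SNR/FWHM/error columns).
#' @export
compareVariants <- function(scan, model, grid, illum, optics,
                            directivity = directivityModel(),
                            profile = NULL, nShells = 50L, nPatches = 200L,
                            epsilon = 0.01, domeRadius = 12) {
  angles <- vapply(scan@planes, poseAngle, numeric(1))
  cache <- computeFluenceCache(illum, optics, grid, angles, nPatches)
  specs <- list(
    neither = list(dir = NULL, comp = FALSE),
    directivity = list(dir = directivity, comp = FALSE),
    compensation = list(dir = NULL, comp = TRUE),
    both = list(dir = directivity, comp = TRUE))
  variants <- lapply(specs, function(s) {
    rec <- reconstructScan(scan, grid, illum = illum, optics = optics,
                           directivity = s$dir, compensation = s$comp,
                           epsilon = epsilon, nPatches = nPatches,
                           fluenceCache = cache)
    out <- list(recon = rec,
                error = imageError(rec, model),
                depth = depthError(rec, model, grid, nShells = nShells,
                                   domeRadius = domeRadius))
    if (!is.null(profile)) {
      pr <- extractProfile(rec, profile$p0, profile$p1,
                           n = if (is.null(profile$n)) 101L else profile$n)
      out$snr <- snrFwhm(abs(pr$values), abs(rec@values), pr$spacing)
    }
    out
  })
  tab <- data.frame(
    variant = names(variants),
    directivity = c(FALSE, TRUE, FALSE, TRUE),
    compensation = c(FALSE, FALSE, TRUE, TRUE),
    image_error = vapply(variants, function(v) v$error, numeric(1)),
    snr_db = vapply(variants, function(v)
      if (is.null(v$snr)) NA_real_ else v$snr$snr_db, numeric(1)),
    fwhm_mm = vapply(variants, function(v)
      if (is.null(v$snr)) NA_real_ else v$snr$fwhm, numeric(1)),
    row.names = NULL)
  list(variants = variants, table = tab)
}
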