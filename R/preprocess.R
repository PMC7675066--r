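## RF conditioning: low-pass filtering, SVD band-noise removal and per-pulse
## energy normalization.  The stage order matters: low-frequency content is
## kept through filtering because the band noise the SVD isolates lives
## there; the back-projection ramp filter removes it afterwards.

#' Zero-phase Butterworth low-pass of an RF plane
#'
#' Filters each channel along time with a Butterworth low-pass applied
#' forward and backward (zero phase, so arrival times used by the
#' back-projection are preserved).  Edges are reflect-padded by one filter
#' length before filtering.
#'
#' @param plane an [rfPlane()].
#' @param order filter order (default 5).
#' @param cutoff cutoff frequency in Hz (default 14.5e6); must be below
#'   Nyquist.
#' @param zeroPhase apply forward-backward (`TRUE`, default) or single-pass
#'   causal filtering.
#' @return The filtered `RFPlane`.
#' @export
lowpass <- function(plane, order = 5L, cutoff = 14.5e6, zeroPhase = TRUE) {
  fs <- plane@samplingRate
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  X <- plane@samples
  ns <- ncol(X)
  npad <- min(ns - 1L, 12L * (order + 1L))
  Y <- t(apply(X, 1, function(x) {
    xp <- c(rev(x[2:(npad + 1)]), x, rev(x[(ns - npad):(ns - 1)]))
    y <- if (zeroPhase) signal::filtfilt(bf, xp)
         else signal::filter(bf, xp)
    y[(npad + 1):(npad + ns)]
  }))
  rfPlane(Y, poseAngle = plane@poseAngle, pulseEnergy = plane@pulseEnergy,
          samplingRate = fs)
}

#' Truncated-SVD band-noise removal
#'
#' Computes the SVD of the channels x time matrix, reconstructs the leading
#' `k` singular components (where the cross-channel band noise concentrates)
#' and subtracts them from the data.  `output + removed = input` holds
#' exactly by construction.
#'
#' @param plane an [rfPlane()].
#' @param k number of leading singular values to discard (default 10, the
#'   value that best balances noise removal against signal loss on real
#'   data).
#' @return A list with `plane` (the denoised `RFPlane`), `removed` (the
#'   subtracted rank-`k` matrix) and `report` (a `DenoiseReport` recording
#'   `k` and the Frobenius energy fraction removed).
#' @export
svdDenoise <- function(plane, k = 10L) {
  X <- plane@samples
  k <- as.integer(k)
  mn <- min(dim(X))
  if (k < 0L || k > mn) stop("k must be between 0 and min(channels, samples)")
  if (k == 0L) {
    rep0 <- new("DenoiseReport", discardedRank = 0L, noiseFraction = 0,
                flagged = FALSE)
    return(list(plane = plane, removed = X * 0, report = rep0))
  }
  sv <- svd(X, nu = k, nv = k)
  noise <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
  frac <- sum(sv$d[seq_len(k)]^2) / max(sum(sv$d^2), .Machine$double.xmin)
  out <- rfPlane(X - noise, poseAngle = plane@poseAngle,
                 pulseEnergy = plane@pulseEnergy,
                 samplingRate = plane@samplingRate)
  list(plane = out, removed = noise,
       report = new("DenoiseReport", discardedRank = k,
                    noiseFraction = frac, flagged = frac > 0.9))
}

setMethod("show", "DenoiseReport", function(object) {
  cat(sprintf("DenoiseReport: rank %d discarded, %.1f%% energy removed%s\n",
              object@discardedRank, 100 * mean(object@noiseFraction),
              if (any(object@flagged)) " [flagged]" else ""))
})

#' Normalize an RF plane by its pulse energy
#'
#' Scales the samples by `referenceEnergy / pulseEnergy`, removing
#' shot-to-shot laser energy variability.
#'
#' @param plane an [rfPlane()].
#' @param referenceEnergy reference energy in mJ (commonly the scan mean).
#' @return The rescaled `RFPlane` with `pulseEnergy = referenceEnergy`.
#' @export
energyNormalize <- function(plane, referenceEnergy) {
  if (plane@pulseEnergy <= 0 || referenceEnergy <= 0)
    stop("pulse energies must be positive")
  rfPlane(plane@samples * (referenceEnergy / plane@pulseEnergy),
          poseAngle = plane@poseAngle, pulseEnergy = referenceEnergy,
          samplingRate = plane@samplingRate)
}

#' Preprocess a full scan
#'
#' Runs the conditioning pipeline on every plane in the fixed order
#' low-pass -> SVD denoise -> energy normalization.  All steps are per-plane
#' and stateless, so the plane order never affects results.
#'
#' @param scan an [RFScan][simulateScan].
#' @param order,cutoff Butterworth parameters (defaults 5, 14.5e6).
#' @param k singular values to discard (default 10).
#' @param referenceEnergy `"mean"` (default) normalizes to the scan-mean
#'   pulse energy; a number fixes the reference explicitly.
#' @param zeroPhase passed to [lowpass()].
#' @return A list with `scan` (the conditioned `RFScan`) and `report`
#'   (a `DenoiseReport` with the per-plane removed-energy fractions).
#' @export
preprocessScan <- function(scan, order = 5L, cutoff = 14.5e6, k = 10L,
                           referenceEnergy = "mean", zeroPhase = TRUE) {
  energies <- vapply(scan@planes, pulseEnergy, numeric(1))
  ref <- if (identical(referenceEnergy, "mean")) mean(energies)
         else as.numeric(referenceEnergy)
  fracs <- numeric(length(scan@planes))
  flags <- logical(length(scan@planes))
  out <- vector("list", length(scan@planes))
  for (i in seq_along(scan@planes)) {
    p <- lowpass(scan@planes[[i]], order = order, cutoff = cutoff,
                 zeroPhase = zeroPhase)
    dn <- svdDenoise(p, k = k)
    fracs[i] <- dn$report@noiseFraction
    flags[i] <- dn$report@flagged
    out[[i]] <- energyNormalize(dn$plane, ref)
  }
  scan@planes <- out
  list(scan = scan,
       report = new("DenoiseReport", discardedRank = as.integer(k),
                    noiseFraction = fracs, flagged = flags))
}
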