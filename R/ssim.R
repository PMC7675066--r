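## Structural similarity (Wang et al. windowed form) for 2D and 3D arrays.
## Local statistics come from a Gaussian window (sigma 1.5, truncated at 3.5
## sigma, edge-replicating padding); the per-window index is
##   S = (2 mu_a mu_b + C1)(2 cov + C2) /
##       ((mu_a^2 + mu_b^2 + C1)(var_a + var_b + C2)),
## averaged over the interior (a border of one window radius is cropped).

.gauss_kernel_1d <- function(sigma, truncate = 3.5) {
  r <- as.integer(truncate * sigma + 0.5)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

## separable correlation along one array dimension with edge replication
.filter_along <- function(x, k, dimIdx) {
  r <- (length(k) - 1L) / 2L
  d <- dim(x)
  n <- d[dimIdx]
  idx <- pmin(pmax(seq(1 - r, n + r), 1L), n)     # replicated index
  perm <- c(dimIdx, seq_along(d)[-dimIdx])
  xp <- aperm(x, perm)
  dim(xp) <- c(n, prod(d[perm[-1]]))
  m <- xp[idx, , drop = FALSE]                    # first dim slices
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * m[j:(j + n - 1), , drop = FALSE]
  res <- array(out, dim = c(n, d[perm[-1]]))
  aperm(res, order(perm))
}

.gauss_filter <- function(x, k) {
  for (dimIdx in seq_along(dim(x))) x <- .filter_along(x, k, dimIdx)
  x
}

#' Structural similarity index
#'
#' Windowed SSIM with the conventional constants (`K1 = 0.01`, `K2 = 0.03`)
#' and a Gaussian weighting window of standard deviation 1.5 samples,
#' matching the reference implementation commonly used for photoacoustic /
#' ultrasound image comparisons.  Works on 2D matrices and 3D arrays.
#'
#' @param a,b arrays of identical shape.
#' @param dataRange dynamic range `L`; defaults to `max(a) - min(a)`.
#' @param sigma Gaussian window standard deviation in samples (default 1.5).
#' @param K1,K2 stabilizer constants (defaults 0.01, 0.03).
#' @return The mean SSIM over the cropped interior, in `[-1, 1]`.
#' @examples
#' a <- outer(sin(1:32 / 3), cos(1:32 / 5), "+")
#' ssim(a, a)
#' @export
ssim <- function(a, b, dataRange = NULL, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  a <- as.array(a); b <- as.array(b)
  if (!identical(dim(a), dim(b))) stop("a and b must have the same shape")
  storage.mode(a) <- "double"; storage.mode(b) <- "double"
  if (is.null(dataRange)) dataRange <- max(a) - min(a)
  if (dataRange <= 0) stop("dynamic range must be positive")
  k <- .gauss_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  ux <- .gauss_filter(a, k); uy <- .gauss_filter(b, k)
  uxx <- .gauss_filter(a * a, k); uyy <- .gauss_filter(b * b, k)
  uxy <- .gauss_filter(a * b, k)
  vx <- uxx - ux * ux; vy <- uyy - uy * uy; vxy <- uxy - ux * uy
  C1 <- (K1 * dataRange)^2; C2 <- (K2 * dataRange)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
       ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  keep <- lapply(dim(S), function(n) {
    if (n <= 2 * r) seq_len(n) else (r + 1):(n - r)
  })
  mean(do.call(`[`, c(list(S), keep)))
}
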