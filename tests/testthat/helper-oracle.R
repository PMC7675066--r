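## Independent, literal transcription of the weighted back-projection sum:
## a plain R triple loop over voxels and elements built from the exported
## geometry primitives.  Used as the oracle the optimized kernel must match.
naiveBackproject <- function(plane, geom, plan, grid, directivity = NULL,
                             interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  fs <- plane@samplingRate
  vs <- plan@soundSpeed * 100
  X <- rfSamples(plane)
  ns <- ncol(X)
  B <- t(apply(X, 1, rampTerm, samplingRate = fs))
  cc <- voxelCenters(grid)
  dims <- gridDim(grid)
  out <- array(0, dim = dims)
  pos <- elementPositions(geom)
  nrm <- elementNormals(geom)
  lat <- elementLaterals(geom)
  for (iz in seq_len(dims[3])) for (iy in seq_len(dims[2]))
    for (ix in seq_len(dims[1])) {
      vox <- c(cc$x[ix], cc$y[iy], cc$z[iz])
      num <- 0; den <- 0
      for (e in seq_len(nElements(geom))) {
        ang <- elementAngles(pos[e, ], nrm[e, ], lat[e, ], vox)
        w <- solidAngleWeight(pos[e, ], nrm[e, ], elementArea(geom), vox)
        if (w <= 0) next
        if (!is.null(directivity))
          w <- w * directivityWeight(ang$thetaL, ang$thetaE, directivity)
        ts <- ang$distance / vs * fs          # 0-based fractional sample
        if (interp == "nearest") {
          k <- round(ts)
          if (k < 0 || k > ns - 1) next
          val <- B[e, k + 1]
        } else {
          k <- floor(ts)
          if (k < 0 || k > ns - 2) next
          f <- ts - k
          val <- B[e, k + 1] * (1 - f) + B[e, k + 2] * f
        }
        num <- num + w * val
        den <- den + w
      }
      out[ix, iy, iz] <- if (den > 0) num / den else 0
    }
  out
}

## tiny synthetic instance shared by the oracle-equivalence tests: distances
## are mapped into a 64-sample window by an artificial sampling rate
tinyInstance <- function(seed = 42, nElem = 8L, n = 16L, ns = 64L) {
  set.seed(seed)
  geom <- buildArray(nElem, arcLength = 8, arcRadius = 12)
  plan <- acquisitionPlan(nAngles = 1L, angularStep = 1.8,
                          samplingRate = 8e5, nSamples = ns)
  grid <- voxelGrid(c(-1.6, -1.6, 7.4), 0.2, rep(n, 3L))
  plane <- rfPlane(matrix(rnorm(nElem * ns), nElem, ns),
                   samplingRate = 8e5)
  list(geom = geom, plan = plan, grid = grid, plane = plane)
}
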