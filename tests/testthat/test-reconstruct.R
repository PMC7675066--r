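test_that("directivity weight is a separable unit-peak Gaussian", {
  m <- directivityModel()          # measured sigmas: 18.5 and 6.2 degrees
  expect_equal(directivityWeight(0, 0, m), 1)
  expect_equal(directivityWeight(18.5, 0, m), exp(-0.5), tolerance = 1e-12)
  expect_equal(directivityWeight(0, 6.2, m), exp(-0.5), tolerance = 1e-12)
  ## separability
  expect_equal(directivityWeight(11, 4, m),
               directivityWeight(11, 0, m) * directivityWeight(0, 4, m),
               tolerance = 1e-12)
  ## disabled model weighs everything 1
  md <- directivityModel(enabled = FALSE)
  expect_equal(directivityWeight(40, 40, md), 1)
  expect_error(directivityModel(sigmaL = -1), "positive")
})

test_that("ramp term matches analytic forms", {
  fs <- 40e6
  n <- 256L
  tt <- (seq_len(n) - 1) / fs
  ## constant signal: derivative vanishes, b = p
  expect_equal(rampTerm(rep(3, n), fs)[2:(n - 1)], rep(3, n - 2))
  ## linear ramp p = a t: b = a t - t a = 0 at interior samples
  b <- rampTerm(5e6 * tt, fs)
  expect_lt(max(abs(b[2:(n - 1)])), 1e-6 * max(abs(5e6 * tt)))
  ## sinusoid: b = sin(wt) - w t cos(wt) to O(dt^2)
  w <- 2 * pi * 1e6
  b <- rampTerm(sin(w * tt), fs)
  truth <- sin(w * tt) - w * tt * cos(w * tt)
  expect_lt(max(abs(b[2:(n - 1)] - truth[2:(n - 1)])) / max(abs(truth)),
            0.005)
  expect_error(rampTerm(c(1, 2), fs), "3 samples")
})

test_that("optimized back-projection equals the literal transcription", {
  inst <- tinyInstance(seed = 7, n = 8L)
  for (dirm in list(NULL, directivityModel())) {
    for (interp in c("linear", "nearest")) {
      fast <- values(backprojectPlane(inst$plane, inst$geom, inst$plan,
                                      inst$grid, dirm, interp))
      slow <- naiveBackproject(inst$plane, inst$geom, inst$plan, inst$grid,
                               dirm, interp)
      expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-9)
    }
  }
  ## an all-zero plane reconstructs to zero
  z <- rfPlane(matrix(0, 8, 64), samplingRate = 8e5)
  expect_true(all(values(backprojectPlane(z, inst$geom, inst$plan,
                                          inst$grid)) == 0))
})

test_that("fluence compensation rescales, masks and accumulates", {
  inst <- tinyInstance(seed = 9, n = 6L)
  vol <- backprojectPlane(inst$plane, inst$geom, inst$plan, inst$grid)
  ## uniform fluence: pure rescale
  uni <- new("FluenceVolume", grid = inst$grid, poseAngle = 0,
             values = array(4, dim = gridDim(inst$grid)))
  acc <- compensateAndAccumulate(vol, uni)
  expect_equal(values(acc), values(vol) / 4, tolerance = 1e-12)
  expect_equal(acc@info$masked, 0)
  expect_equal(acc@kind, "absorption")
  ## zero fluence masks everything
  zero <- new("FluenceVolume", grid = inst$grid, poseAngle = 0,
              values = array(0, dim = gridDim(inst$grid)))
  acc0 <- compensateAndAccumulate(vol, zero)
  expect_true(all(values(acc0) == 0))
  expect_equal(acc0@info$masked, prod(gridDim(inst$grid)))
  ## dim fluence below epsilon * max is masked, not amplified
  psi <- array(1, dim = gridDim(inst$grid)); psi[1, 1, 1] <- 1e-6
  fv <- new("FluenceVolume", grid = inst$grid, poseAngle = 0, values = psi)
  accm <- compensateAndAccumulate(vol, fv, epsilon = 0.01)
  expect_equal(accm@info$masked, 1)
  expect_equal(values(accm)[1, 1, 1], 0)
  ## grid mismatch is refused
  g2 <- voxelGrid(gridOrigin(inst$grid) + 0.05, gridSpacing(inst$grid),
                  gridDim(inst$grid))
  bad <- new("FluenceVolume", grid = g2, poseAngle = 0,
             values = array(1, dim = gridDim(g2)))
  expect_error(compensateAndAccumulate(vol, bad), "do not match")
})

test_that("scan reconstruction is linear and order-independent", {
  geom <- buildArray(8)
  ill <- buildIlluminator()
  op <- opticalProperties(0.2, 10)
  ph <- phantomFixture("point_source")
  grid <- voxelGrid(c(-0.4, -0.4, 8.6), 0.1, c(9L, 9L, 9L))
  ns <- requiredSamples(geom, grid, acquisitionPlan(nSamples = 2L))
  plan <- acquisitionPlan(nAngles = 4L, angularStep = 90, nSamples = ns)
  scan <- simulateScan(ph, geom, ill, plan, optics = op)
  rec <- reconstructScan(scan, grid, illum = ill, optics = op,
                         compensation = TRUE, nPatches = 50)
  ## linearity in the RF amplitude
  scan2 <- scan
  scan2@planes <- lapply(planes(scan), function(p) {
    rfSamples(p) <- rfSamples(p) * 2.5; p
  })
  rec2 <- reconstructScan(scan2, grid, illum = ill, optics = op,
                          compensation = TRUE, nPatches = 50)
  expect_equal(values(rec2), 2.5 * values(rec), tolerance = 1e-9)
  ## pose order does not matter
  scan3 <- scan
  scan3@planes <- scan@planes[c(3, 1, 4, 2)]
  rec3 <- reconstructScan(scan3, grid, illum = ill, optics = op,
                          compensation = TRUE, nPatches = 50)
  expect_lt(max(abs(values(rec3) - values(rec))) / max(abs(values(rec))),
            1e-9)
  ## single pose with uniform fluence is a pure rescale of the plane volume
  plan1 <- acquisitionPlan(nAngles = 1L, nSamples = ns)
  sc1 <- simulateScan(ph, geom, ill, plan1)
  uni <- new("FluenceVolume", grid = grid, poseAngle = 0,
             values = array(2, dim = gridDim(grid)))
  cache <- list("0.000000" = uni)
  r1 <- reconstructScan(sc1, grid, compensation = TRUE,
                        fluenceCache = cache)
  bp <- backprojectPlane(planes(sc1)[[1]], geom, plan1, grid)
  expect_equal(values(r1), values(bp) / 2, tolerance = 1e-12)
})

test_that("compensation recovers relative absorption under fan illumination", {
  ## two absorbers with a 2:1 absorption ratio at equal depth in the imaging
  ## plane of a single pose, one nearer the illuminated window than the
  ## other.  The arc's own point-spread asymmetry is calibrated out with a
  ## uniformly lit 1:1 reference scan of the same geometry (the system is
  ## linear), isolating the illumination bias.
  geom <- buildArray(48)
  ill <- buildIlluminator()
  op <- opticalProperties(0.0075, 15)   # milk/water bath
  A <- c(-1.2, 0, 9.5); B <- c(1.2, 0, 9.5)
  mkph <- function(absA, absB) phantomModel(data.frame(
    x0 = c(A[1], B[1]), y0 = c(A[2], B[2]), z0 = c(A[3], B[3]),
    x1 = c(A[1], B[1]), y1 = c(A[2], B[2]), z1 = c(A[3], B[3]) + 0.01,
    radius = 0.0125, absorption = c(absA, absB)))
  grid <- voxelGrid(c(-1.5, -0.2, 9.2), 0.1, c(31L, 5L, 7L))
  ns <- requiredSamples(geom, grid, acquisitionPlan(nSamples = 2L))
  plan <- acquisitionPlan(nAngles = 1L, nSamples = ns)
  at <- function(vol, p) {
    idx <- round((p - gridOrigin(grid)) / gridSpacing(grid)) + 1
    values(vol)[idx[1], idx[2], idx[3]]
  }
  ## point-spread calibration: equal absorbers, uniform light
  ref <- reconstructScan(simulateScan(mkph(1, 1), geom, ill, plan), grid)
  psf_ratio <- at(ref, A) / at(ref, B)
  ## fan-illuminated 2:1 scan
  scan <- simulateScan(mkph(2, 1), geom, ill, plan, optics = op)
  psi <- fluenceAtPoints(rbind(A, B), ill, op)
  recU <- reconstructScan(scan, grid)                       # uncompensated
  recC <- reconstructScan(scan, grid, illum = ill, optics = op,
                          compensation = TRUE)
  ratioU <- at(recU, A) / at(recU, B) / psf_ratio
  ratioC <- at(recC, A) / at(recC, B) / psf_ratio
  ## compensated ratio within 15% of the true 2:1
  expect_lt(abs(ratioC - 2) / 2, 0.15)
  ## uncompensated ratio is biased by the fluence ratio at the positions
  expect_equal(sign(ratioU - 2), sign(psi[1] / psi[2] - 1))
  expect_gt(abs(ratioU - 2) / 2, abs(ratioC - 2) / 2)
})
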