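test_that("voxelization reproduces wire geometry", {
  g <- voxelGrid(c(-1, -1, 9), 0.05, c(41L, 41L, 41L))
  ## empty phantom: all background
  empty <- phantomModel(data.frame(x0 = numeric(), y0 = numeric(),
                                   z0 = numeric(), x1 = numeric(),
                                   y1 = numeric(), z1 = numeric(),
                                   radius = numeric(),
                                   absorption = numeric()),
                        backgroundAbsorption = 0.3)
  ve <- voxelizePhantom(empty, g)
  expect_true(all(values(ve) == 0.3))
  ## axis-aligned cylinder: voxel count approximates the analytic volume
  ## (2.5-voxel radius keeps the lattice-boundary jitter below the bound)
  r <- 2.5 * 0.05
  ph <- phantomModel(data.frame(x0 = -0.8, y0 = 0, z0 = 9.5, x1 = 0.8,
                                y1 = 0, z1 = 9.5, radius = r,
                                absorption = 2))
  v <- values(voxelizePhantom(ph, g))
  count <- sum(v == 2)
  ## distance-to-segment marks a capsule: cylinder plus hemispherical caps
  analytic <- (pi * r^2 * 1.6 + 4 / 3 * pi * r^3) / 0.05^3
  expect_lt(abs(count - analytic) / analytic, 0.15)
  ## two parallel wires separated by > 2 radii stay disjoint
  ph2 <- phantomModel(data.frame(
    x0 = c(-0.8, -0.8), y0 = c(-0.3, 0.3), z0 = 9.5,
    x1 = c(0.8, 0.8), y1 = c(-0.3, 0.3), z1 = 9.5,
    radius = 0.06, absorption = 1))
  v2 <- values(voxelizePhantom(ph2, g))
  ys <- voxelCenters(g)$y[which(v2 > 0, arr.ind = TRUE)[, 2]]
  expect_true(all(abs(ys) > 0.1))          # nothing in the gap
  expect_true(any(ys < 0) && any(ys > 0))  # both wires present
  ## out-of-grid wire warns
  ph3 <- phantomModel(data.frame(x0 = 5, y0 = 5, z0 = 5, x1 = 6, y1 = 6,
                                 z1 = 6, radius = 0.05, absorption = 1))
  expect_warning(voxelizePhantom(ph3, g), "outside")
})

test_that("forward RF peaks at the geometric delay", {
  geom <- buildArray(16)
  src <- c(0.4, -0.2, 9.1)
  ph <- phantomModel(data.frame(x0 = src[1], y0 = src[2], z0 = src[3],
                                x1 = src[1], y1 = src[2], z1 = src[3],
                                radius = 0.0125, absorption = 1))
  grid <- voxelGrid(src - 0.2, 0.1, c(5L, 5L, 5L))
  ns <- requiredSamples(geom, grid, acquisitionPlan(nSamples = 2L))
  plan <- acquisitionPlan(nAngles = 1L, nSamples = ns)
  pl <- forwardRF(ph, geom, plan)
  X <- rfSamples(pl)
  vs <- plan@soundSpeed * 100
  for (e in c(1L, 8L, 16L)) {
    d <- sqrt(sum((src - elementPositions(geom)[e, ])^2))
    delay <- round(d / vs * plan@samplingRate) + 1L
    ## the N-wave's lobes straddle the geometric delay within 2 samples
    expect_lte(abs(which.max(abs(X[e, ])) - delay), 2L)
    ## single arrival event: silence away from the delay
    keep <- abs(seq_along(X[e, ]) - delay) > 15
    expect_lt(max(abs(X[e, keep])), 1e-6 * max(abs(X[e, ])))
  }
})

test_that("forward model is linear in absorption and fluence", {
  geom <- buildArray(8)
  ph <- phantomFixture("point_source")
  grid <- voxelGrid(c(-0.3, -0.3, 8.7), 0.1, c(7L, 7L, 7L))
  ns <- requiredSamples(geom, grid, acquisitionPlan(nSamples = 2L))
  plan <- acquisitionPlan(nAngles = 1L, nSamples = ns)
  X1 <- rfSamples(forwardRF(ph, geom, plan))
  ## doubling the fluence doubles every sample
  X2 <- rfSamples(forwardRF(ph, geom, plan, fluence = 2))
  expect_equal(X2, 2 * X1, tolerance = 1e-12)
  ## zero absorption gives silence
  ph0 <- phantomModel(ph@wires[0, ])
  expect_true(all(rfSamples(forwardRF(ph0, geom, plan)) == 0))
  ## superposition over phantoms
  phA <- phantomModel(data.frame(x0 = 0.2, y0 = 0, z0 = 8.9, x1 = 0.2,
                                 y1 = 0, z1 = 8.91, radius = 0.0125,
                                 absorption = 1))
  phB <- phantomModel(data.frame(x0 = -0.2, y0 = 0.1, z0 = 8.8, x1 = -0.2,
                                 y1 = 0.1, z1 = 8.81, radius = 0.0125,
                                 absorption = 0.5))
  phAB <- phantomModel(rbind(phA@wires, phB@wires))
  XA <- rfSamples(forwardRF(phA, geom, plan))
  XB <- rfSamples(forwardRF(phB, geom, plan))
  XAB <- rfSamples(forwardRF(phAB, geom, plan))
  expect_equal(XAB, XA + XB, tolerance = 1e-9 * max(abs(XAB)))
  ## too-short time window is refused
  expect_error(forwardRF(ph, geom, acquisitionPlan(nSamples = 100L)),
               "time window")
})

test_that("structured noise is reproducible, low-rank and optional", {
  pl <- rfPlane(matrix(0, 32, 256), samplingRate = 40e6)
  ## no-op model
  nm0 <- noiseModel(bandCount = 0L, bandAmplitude = 0, whiteSigma = 0,
                    energyJitter = 0)
  expect_identical(rfSamples(addNoise(pl, nm0)), rfSamples(pl))
  ## a single rank-1 band on zero input has numerical rank 1
  nm1 <- noiseModel(bandCount = 1L, bandRank = 1L, bandAmplitude = 2,
                    whiteSigma = 0, energyJitter = 0, seed = 5L)
  X <- rfSamples(addNoise(pl, nm1))
  sv <- svd(X)$d
  expect_gt(sv[1], 0)
  expect_lt(sv[2] / sv[1], 1e-12)
  ## bitwise determinism for a fixed seed
  nm <- noiseModel(bandCount = 3L, bandAmplitude = 1, whiteSigma = 0.2,
                   seed = 99L)
  expect_identical(rfSamples(addNoise(pl, nm)), rfSamples(addNoise(pl, nm)))
  ## jitter is recorded in the pulse energy
  nmj <- noiseModel(bandCount = 0L, bandAmplitude = 0, whiteSigma = 0,
                    energyJitter = 0.15, seed = 3L)
  out <- addNoise(pl, nmj)
  expect_false(pulseEnergy(out) == 1)
  expect_lt(abs(pulseEnergy(out) - 1), 0.15 + 1e-12)
})

test_that("simulateScan composes poses consistently", {
  geom <- buildArray(8)
  ill <- buildIlluminator()
  ph <- phantomFixture("point_source")
  grid <- voxelGrid(c(-0.3, -0.3, 8.7), 0.1, c(7L, 7L, 7L))
  ns <- requiredSamples(geom, grid, acquisitionPlan(nSamples = 2L))
  ## single pose equals forwardRF at pose 0
  plan1 <- acquisitionPlan(nAngles = 1L, nSamples = ns)
  sc1 <- simulateScan(ph, geom, ill, plan1)
  expect_equal(rfSamples(planes(sc1)[[1]]),
               rfSamples(forwardRF(ph, geom, plan1)), tolerance = 1e-12)
  ## pose angles follow the plan (paper protocol: 200 poses at 1.8 deg)
  plan200 <- acquisitionPlan(nAngles = 200L, angularStep = 1.8,
                             nSamples = ns)
  sc200 <- simulateScan(ph, geom, ill, plan200)
  expect_length(planes(sc200), 200)
  expect_equal(vapply(planes(sc200), poseAngle, numeric(1)),
               (0:199) * 1.8)
  ## wire on the rotation axis: noise-free planes identical at all poses
  axwire <- phantomModel(data.frame(x0 = 0, y0 = 0, z0 = 8.8, x1 = 0,
                                    y1 = 0, z1 = 9.2, radius = 0.0125,
                                    absorption = 1))
  plan4 <- acquisitionPlan(nAngles = 4L, angularStep = 90, nSamples = ns)
  sc4 <- simulateScan(axwire, geom, ill, plan4, optics = NULL)
  ref <- rfSamples(planes(sc4)[[1]])
  for (k in 2:4)
    expect_lt(max(abs(rfSamples(planes(sc4)[[k]]) - ref)) / max(abs(ref)),
              1e-6)
})
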