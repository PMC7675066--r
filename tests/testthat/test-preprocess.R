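test_that("Butterworth low-pass preserves the passband and kills the stopband", {
  fs <- 40e6; ns <- 1024L
  tt <- (seq_len(ns) - 1) / fs
  ## DC channel is unchanged
  pl <- rfPlane(matrix(1, 2, ns), samplingRate = fs)
  out <- lowpass(pl)
  expect_lt(max(abs(rfSamples(out) - 1)), 1e-6)
  ## an 18 MHz tone is attenuated at least as much as the analytic
  ## single-pass Butterworth magnitude at 18/14.5 normalized frequency
  tone <- sin(2 * pi * 18e6 * tt)
  plt <- rfPlane(rbind(tone, tone), samplingRate = fs)
  y <- rfSamples(lowpass(plt))[1, ]
  mid <- 300:700
  gain <- max(abs(y[mid])) / max(abs(tone[mid]))
  analytic <- 1 / sqrt(1 + (18 / 14.5)^(2 * 5))
  expect_lt(gain, analytic)
  ## linearity
  set.seed(1)
  a <- matrix(rnorm(2 * ns), 2, ns); b <- matrix(rnorm(2 * ns), 2, ns)
  fa <- rfSamples(lowpass(rfPlane(a, samplingRate = fs)))
  fb <- rfSamples(lowpass(rfPlane(b, samplingRate = fs)))
  fab <- rfSamples(lowpass(rfPlane(a + b, samplingRate = fs)))
  expect_lt(max(abs(fab - fa - fb)), 1e-9 * max(abs(fab)))
  ## cutoff must be below Nyquist
  expect_error(lowpass(pl, cutoff = 25e6), "Nyquist")
})

test_that("SVD denoising removes low-rank bands and conserves energy", {
  set.seed(2)
  nch <- 64L; ns <- 512L
  ## k = 0 is the identity
  pl <- rfPlane(matrix(rnorm(nch * ns), nch, ns), samplingRate = 40e6)
  expect_identical(rfSamples(svdDenoise(pl, 0)$plane), rfSamples(pl))
  ## removing min(dims) components leaves nothing
  plSmall <- rfPlane(matrix(rnorm(6 * 40), 6, 40), samplingRate = 40e6)
  expect_lt(max(abs(rfSamples(svdDenoise(plSmall, 6)$plane))), 1e-9)
  expect_error(svdDenoise(plSmall, 7), "between 0")
  ## conservation: output + removed = input
  dn <- svdDenoise(pl, 5)
  expect_lt(max(abs(rfSamples(dn$plane) + dn$removed - rfSamples(pl))) /
            max(abs(rfSamples(pl))), 1e-9)
  expect_equal(dn$report@discardedRank, 5L)
  expect_gte(dn$report@noiseFraction, 0)
  expect_lte(dn$report@noiseFraction, 1)
  ## a dominant rank-1 band (100x the signal) is suppressed below 1%
  ## with < 5% signal distortion at k = 1
  signal <- matrix(rnorm(nch * ns), nch, ns)
  band <- 100 * outer(exp(-0.5 * ((seq_len(nch) - 30) / 8)^2),
                      sin(2 * pi * 3e6 * (seq_len(ns) - 1) / 40e6))
  bandE <- sum(band^2)
  noisy <- rfPlane(signal + band, samplingRate = 40e6)
  out <- rfSamples(svdDenoise(noisy, 1)$plane)
  bhat <- band / sqrt(bandE)
  resid <- sum(out * bhat)^2
  expect_lt(resid / bandE, 0.01)
  ## signal Frobenius energy is nearly conserved (the unavoidable cost is
  ## the signal's own component inside the discarded rank-1 subspace)
  sigF <- sqrt(sum(signal^2))
  expect_lt(abs(sqrt(sum(out^2)) - sigF) / sigF, 0.05)
})

test_that("energy normalization rescales by pulse energy", {
  X <- matrix(rnorm(40), 4, 10)
  pl <- rfPlane(X, pulseEnergy = 2, samplingRate = 40e6)
  ## reference equal to the pulse energy is the identity
  expect_equal(rfSamples(energyNormalize(pl, 2)), X)
  ## double energy halves the samples
  expect_equal(rfSamples(energyNormalize(pl, 1)), X / 2)
  expect_error(energyNormalize(pl, -1), "positive")
  expect_error(energyNormalize(rfPlane(X, pulseEnergy = 1), 0), "positive")
})

test_that("normalization reduces inter-plane spread of a fixed source", {
  geom <- buildArray(8)
  ill <- buildIlluminator()
  axwire <- phantomModel(data.frame(x0 = 0, y0 = 0, z0 = 8.8, x1 = 0,
                                    y1 = 0, z1 = 9.2, radius = 0.0125,
                                    absorption = 1))
  grid <- voxelGrid(c(-0.2, -0.2, 8.7), 0.1, c(5L, 5L, 7L))
  ns <- requiredSamples(geom, grid, acquisitionPlan(nSamples = 2L))
  plan <- acquisitionPlan(nAngles = 12L, angularStep = 30, nSamples = ns)
  nm <- noiseModel(bandCount = 0L, bandAmplitude = 0, whiteSigma = 0,
                   energyJitter = 0.15, seed = 21L)
  sc <- simulateScan(axwire, geom, ill, plan, noise = nm)
  amp <- function(planes) vapply(planes, function(p)
    max(abs(rfSamples(p))), numeric(1))
  cv <- function(x) sd(x) / mean(x)
  raw_cv <- cv(amp(planes(sc)))
  norm_cv <- cv(amp(planes(preprocessScan(sc, k = 0L)$scan)))
  expect_lt(norm_cv / raw_cv, 1)
})

test_that("the conditioning pipeline applies lowpass, SVD, normalization in order", {
  set.seed(4)
  geom <- buildArray(6)
  pl1 <- rfPlane(matrix(rnorm(6 * 256), 6, 256), pulseEnergy = 1.2,
                 samplingRate = 40e6)
  pl2 <- rfPlane(matrix(rnorm(6 * 256), 6, 256), pulseEnergy = 0.9,
                 samplingRate = 40e6)
  scan <- new("RFScan", planes = list(pl1, pl2),
              plan = acquisitionPlan(nAngles = 2L, angularStep = 180,
                                     nSamples = 256L),
              geometry = geom, illuminator = buildIlluminator())
  pp <- preprocessScan(scan, k = 3L)
  ## manual composition in the documented order, same reference energy
  ref <- mean(c(1.2, 0.9))
  manual <- energyNormalize(svdDenoise(lowpass(pl1), 3L)$plane, ref)
  expect_equal(rfSamples(planes(pp$scan)[[1]]), rfSamples(manual),
               tolerance = 1e-12)
  ## stateless per-plane processing: plane order does not matter
  scan_rev <- scan; scan_rev@planes <- list(pl2, pl1)
  pp_rev <- preprocessScan(scan_rev, k = 3L)
  expect_equal(rfSamples(planes(pp_rev$scan)[[2]]),
               rfSamples(planes(pp$scan)[[1]]), tolerance = 1e-12)
  expect_length(pp$report@noiseFraction, 2)
})
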