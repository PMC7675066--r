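test_that("SNR/FWHM follow the half-maximum peak-region definition", {
  img <- array(0, dim = c(20, 20, 1)); img[5, 5, 1] <- 1  # nonzero spread
  ## rectangular pulse of width 7 samples
  prof <- rep(0, 50); prof[20:26] <- 1
  m <- snrFwhm(prof, img, spacing = 0.5)
  expect_equal(m$fwhm, 7 * 0.5)
  expect_equal(m$peakRegion, c(20, 26))
  ## Gaussian profile: FWHM = 2.3548 sigma within one sample
  sg <- 4
  prof <- exp(-0.5 * ((1:101 - 51) / sg)^2)
  m <- snrFwhm(prof, img, spacing = 1)
  expect_lt(abs(m$fwhm - 2.3548 * sg), 1)
  ## SNR is scale-invariant (ratio of amplitudes)
  m10 <- snrFwhm(10 * prof, 10 * img, spacing = 1)
  expect_equal(m10$snr_db, m$snr_db, tolerance = 1e-9)
  ## dB convention: 20 log10 of the amplitude ratio
  expect_equal(m$snr_db, 20 * log10(m$snr), tolerance = 1e-12)
  ## flat profile has no peak
  expect_error(snrFwhm(rep(1, 10), img, 1), "no positive peak")
  expect_error(snrFwhm(rep(0, 10), img, 1), "no positive peak")
})

test_that("RMSE identities", {
  set.seed(3)
  a <- array(rnorm(4^3), dim = rep(4, 3))
  b <- array(rnorm(4^3), dim = rep(4, 3))
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(a, b), rmse(b, a))
  ## single-voxel difference d in N voxels: d / sqrt(N)
  d <- 0.7
  b1 <- a; b1[2, 3, 1] <- a[2, 3, 1] + d
  expect_equal(rmse(a, b1), d / sqrt(64), tolerance = 1e-12)
  expect_error(rmse(a, array(0, dim = c(2, 2, 2))), "shape")
})

test_that("SSIM matches the windowed reference form", {
  ## deterministic fixture; the expected value was computed independently
  ## with the scikit-image implementation (gaussian window, sigma 1.5)
  i <- matrix(1:32, 32, 32); j <- t(i)
  a <- sin(i / 3) + cos(j / 5)
  b <- a + 0.1 * sin((i + j) / 2)
  expect_equal(ssim(a, b), 0.9583993502720609, tolerance = 1e-6)
  ## self-similarity is exactly 1 and symmetric
  expect_equal(ssim(a, a), 1)
  dr <- max(a, b) - min(a, b)
  expect_equal(ssim(a, b, dataRange = dr), ssim(b, a, dataRange = dr),
               tolerance = 1e-12)
  ## full contrast inversion of a locally zero-mean pattern is negative
  ## (reference value -0.99641 from the same oracle)
  ck <- outer(0:31, 0:31, function(x, y) ifelse((x + y) %% 2 == 0, 1, -1))
  expect_equal(ssim(ck, -ck, dataRange = 2), -0.9964064683532639,
               tolerance = 1e-6)
  expect_lt(ssim(ck, -ck, dataRange = 2), 0)
  ## constant offset penalizes luminance: close to, but below, 1
  off <- a + 0.02 * (max(a) - min(a))
  s <- ssim(a, off, dataRange = max(a) - min(a))
  expect_lt(s, 1); expect_gt(s, 0.8)
  expect_error(ssim(a, b[1:16, 1:16]), "shape")
})

test_that("relative image error follows the two-norm ratio", {
  set.seed(5)
  m <- array(0, dim = rep(6, 3)); m[3, 3, 3] <- 1; m[4, 3, 3] <- 1
  expect_equal(imageError(m, m), 0)
  expect_equal(imageError(array(0, dim = dim(m)), m), 1)
  ## without normalization, a = 2m doubles the numerator norm
  expect_equal(imageError(2 * m, m, normalize = "none"), 1)
  ## unit-max normalization makes the metric scale-consistent
  a <- array(runif(6^3), dim = rep(6, 3))
  expect_equal(imageError(3 * a, 2 * m), imageError(a, m),
               tolerance = 1e-12)
  expect_error(imageError(a, array(0, dim = dim(a))), "all zero")
})

test_that("depth shells partition the volume and recombine to the global error", {
  set.seed(6)
  g <- voxelGrid(c(-1.5, -1.5, 8.5), 0.25, c(13L, 13L, 13L))
  m <- array(0, dim = gridDim(g))
  m[4:10, 7, c(3, 7, 11)] <- 1
  a <- m + array(rnorm(prod(gridDim(g)), sd = 0.1), dim = gridDim(g))
  ## identical volumes: zero everywhere it is defined
  de0 <- depthError(m, m, g)
  expect_true(all(de0$error[!is.na(de0$error)] == 0))
  ## a single shell reproduces the global image error
  de1 <- depthError(a, m, g, nShells = 1L)
  expect_equal(de1$error, imageError(a, m), tolerance = 1e-12)
  ## shells partition: counts sum to the voxel total
  de <- depthError(a, m, g, nShells = 50L)
  expect_equal(sum(de$count), prod(gridDim(g)))
  ## numerator/denominator sums recombine to the global error
  expect_equal(sqrt(sum(de$num2)) / sqrt(sum(de$den2)),
               imageError(a, m), tolerance = 1e-9)
  ## empty-model shells are marked missing, not zero
  expect_true(any(is.na(de$error)))
})

test_that("profiles extract trilinear line samples", {
  g <- voxelGrid(c(0, 0, 0), 1, c(5L, 5L, 5L))
  v <- array(0, dim = c(5, 5, 5))
  v[] <- rep(0:4, each = 1)   # linear in x
  pr <- extractProfile(v, c(0, 2, 2), c(4, 2, 2), n = 9, grid = g)
  expect_equal(pr$values, seq(0, 4, by = 0.5), tolerance = 1e-12)
  expect_equal(pr$spacing, 4 / 8 * 10)   # cm -> mm
})

test_that("variant comparison ranks reconstructions on an easy phantom", {
  geom <- buildArray(24)
  ill <- buildIlluminator()
  op <- opticalProperties(0.2, 10)
  dirm <- directivityModel()
  ph <- phantomModel(data.frame(x0 = 0, y0 = -0.6, z0 = 9.4, x1 = 0,
                                y1 = 0.6, z1 = 9.4, radius = 0.0125,
                                absorption = 1))
  grid <- voxelGrid(c(-0.7, -0.7, 8.7), 0.1, c(15L, 15L, 15L))
  ns <- requiredSamples(geom, grid, acquisitionPlan(nSamples = 2L))
  plan <- acquisitionPlan(nAngles = 8L, angularStep = 45, nSamples = ns)
  scan <- simulateScan(ph, geom, ill, plan, optics = op,
                       directivity = dirm)
  model <- voxelizePhantom(ph, grid)
  cmp <- compareVariants(scan, model, grid, ill, op, dirm,
                         profile = list(p0 = c(-0.7, 0, 9.4),
                                        p1 = c(0.7, 0, 9.4), n = 57),
                         nShells = 10L, nPatches = 100L)
  expect_setequal(names(cmp$variants),
                  c("neither", "directivity", "compensation", "both"))
  ## all four variants localize the inclusion with a finite FWHM
  expect_true(all(is.finite(cmp$table$fwhm_mm)))
  expect_true(all(is.finite(cmp$table$snr_db)))
  expect_true(all(cmp$table$image_error >= 0))
  ## determinism: rerunning gives identical metrics
  cmp2 <- compareVariants(scan, model, grid, ill, op, dirm,
                          nShells = 10L, nPatches = 100L)
  expect_equal(cmp2$table$image_error, cmp$table$image_error,
               tolerance = 1e-12)
})
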