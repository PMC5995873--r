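test_that("empty fiber spec yields an all-background volume", {
  ph <- generateFibers(c(32, 32, 32), 1.8, fiberSpec(0), seed = 1)
  expect_equal(unname(sum(ph$truth@materialVoxels)), 0)
  expect_true(all(volumeData(ph$volume) == 30))
  expect_equal(nrow(ph$truth@fibers), 0)
})

test_that("cylinder rasterization matches the brute-force voxel oracle", {
  spec <- fiberSpec(1, radius = 5, orientationMode = "aligned",
                    alignedAzimuth = 0, angularJitter = 0,
                    latitudeRange = c(90, 90))
  ph <- generateFibers(c(64, 64, 64), 1, spec, seed = 1)
  arr <- volumeData(ph$volume)
  fb <- ph$truth@fibers
  oracle <- cylinderVoxelOracle(c(64, 64, 64),
                                c(fb$anchorX, fb$anchorY, fb$anchorZ),
                                c(fb$dirX, fb$dirY, fb$dirZ), 5)
  expect_equal(sum(arr == 100), oracle)
  expect_equal(unname(ph$truth@materialVoxels[["fiber"]]), oracle)
  # one radius-5 fiber along x through a 64^3 grid occupies ~ pi*25/64^2
  expect_equal(mean(arr == 100), pi * 25 / 64^2, tolerance = 0.05)
})

test_that("phantom generation is bit-reproducible and seed-sensitive", {
  spec <- fiberSpec(5, radius = list(kind = "uniform", min = 4, max = 10))
  a <- generateFibers(c(32, 32, 32), 1.8, spec, seed = 11)
  b <- generateFibers(c(32, 32, 32), 1.8, spec, seed = 11)
  c <- generateFibers(c(32, 32, 32), 1.8, spec, seed = 12)
  expect_identical(volumeData(a$volume), volumeData(b$volume))
  expect_identical(a$truth@fibers, b$truth@fibers)
  expect_false(identical(volumeData(a$volume), volumeData(c$volume)))
})

test_that("aligned mode with zero jitter fixes every azimuth", {
  spec <- fiberSpec(8, radius = 4, orientationMode = "aligned",
                    alignedAzimuth = 45, angularJitter = 0)
  ph <- generateFibers(c(32, 32, 32), 1, spec, seed = 3)
  expect_equal(ph$truth@fibers$theta, rep(45, 8))
})

test_that("unresolvable radii and bad calibration are rejected", {
  expect_error(generateFibers(c(32, 32, 32), 1.8, fiberSpec(1, radius = 1),
                              seed = 1), "unresolvable")
  expect_error(generateFibers(c(32, 32, 32), 0, fiberSpec(1, radius = 5),
                              seed = 1), "voxelSize")
  expect_error(generateFibers(c(16, 32, 32), 1, fiberSpec(1, radius = 5),
                              seed = 1), "32")
})

test_that("random orientation mode gives a uniform azimuth distribution", {
  spec <- fiberSpec(600, radius = 2, orientationMode = "random")
  # draw angles only (rasterizing 600 fibers is unnecessary for this check)
  th <- withr::with_seed(99, scaffoldCT:::sampleFiberAngles(spec)$theta)
  cs <- suppressWarnings(
    chisq.test(tabulate(findInterval(th, seq(0, 180, 20)), 9)))
  expect_gt(cs$p.value, 0.01)
})

test_that("sphere rasterization and aggregate bookkeeping are exact", {
  base <- generateFibers(c(64, 64, 64), 1, fiberSpec(0), seed = 1)
  vol <- 4 / 3 * pi * 4^3  # radius 4 voxels at 1 µm voxels
  pp <- addParticles(base$volume, base$truth,
                     particleSpec(1, volume = vol, clustering = 0), seed = 5)
  tr <- pp$truth
  oracle <- sphereVoxelOracle(c(64, 64, 64),
                              c(tr@particles$centerX, tr@particles$centerY,
                                tr@particles$centerZ), 4)
  expect_equal(tr@aggregates$voxelCount, oracle)
  expect_equal(unname(tr@materialVoxels[["particle"]]), oracle)
  expect_equal(sum(volumeData(pp$volume) == 220), oracle)
})

test_that("full clustering forms a single 18-connected aggregate", {
  base <- generateFibers(c(64, 64, 64), 1, fiberSpec(0), seed = 1)
  pp <- addParticles(base$volume, base$truth,
                     particleSpec(3, volume = 268, clustering = 1), seed = 9)
  expect_equal(nrow(pp$truth@aggregates), 1)
  m <- volumeData(pp$volume) == 220
  expect_equal(labelComponents(array(m, dim(m)), 18)$n, 1)
})

test_that("zero particles leave the volume untouched", {
  base <- generateFibers(c(32, 32, 32), 1.8, fiberSpec(2, radius = 5),
                         seed = 2)
  pp <- addParticles(base$volume, base$truth, particleSpec(0), seed = 3)
  expect_identical(volumeData(pp$volume), volumeData(base$volume))
  expect_equal(nrow(pp$truth@particles), 0)
})

test_that("sub-voxel particles are recorded and flagged", {
  base <- generateFibers(c(32, 32, 32), 1.8, fiberSpec(0), seed = 1)
  pp <- addParticles(base$volume, base$truth,
                     particleSpec(2, volume = 2), seed = 4)  # < 5.83 µm³
  expect_true(all(pp$truth@particles$subResolution))
  expect_equal(nrow(pp$truth@particles), 2)
})

test_that("degradation is identity at zero blur and noise", {
  ph <- generateFibers(c(32, 32, 32), 1.8, fiberSpec(2, radius = 5), seed = 1)
  out <- degradeVolume(ph$volume, 0, 0, seed = 1)
  expect_identical(volumeData(out), volumeData(ph$volume))
})

test_that("normalized blur preserves constant volumes", {
  const <- VoxelVolume(array(77, c(32, 32, 32)), 1.8)
  out <- degradeVolume(const, blurSigma = 3.6, noiseSd = 0, seed = 1)
  expect_equal(volumeData(out), volumeData(const), tolerance = 1e-12)
})

test_that("additive noise has the stated standard deviation", {
  const <- VoxelVolume(array(120, c(64, 64, 32)), 1.8)  # > 1e5 voxels
  out <- degradeVolume(const, 0, noiseSd = 10, seed = 2)
  s <- sd(volumeData(out))  # far from clip bounds: clipping inactive
  expect_gt(s, 9.5)
  expect_lt(s, 10.5)
  out2 <- degradeVolume(const, 0, noiseSd = 10, seed = 2)
  expect_identical(volumeData(out), volumeData(out2))
})

test_that("noiseless material fraction equals the truth voxel counts", {
  spec <- fiberSpec(6, radius = list(kind = "uniform", min = 3, max = 8))
  ph <- generateFibers(c(48, 48, 48), 1.5, spec, seed = 21)
  pp <- addParticles(ph$volume, ph$truth, particleSpec(4, volume = 300),
                     seed = 22)
  arr <- volumeData(pp$volume)
  expect_identical(sum(arr != 30), as.integer(sum(pp$truth@materialVoxels)))
})

test_that("truth summary agrees with analytic geometry", {
  spec <- fiberSpec(1, radius = 5, orientationMode = "aligned",
                    alignedAzimuth = 0, angularJitter = 0,
                    latitudeRange = c(90, 90))
  ph <- generateFibers(c(64, 64, 64), 1, spec, seed = 1)
  ts <- truthSummary(ph$truth)
  # analytic cylinder porosity within the attached discretization bound
  expect_lt(abs(ts$porosity$exact - ts$porosity$analytic),
            ts$porosity$discretizationBound)
  expect_equal(nrow(ts$particleSizes), 0)

  spec90 <- fiberSpec(5, radius = 4, orientationMode = "aligned",
                      alignedAzimuth = 90, angularJitter = 0)
  ph90 <- generateFibers(c(32, 32, 32), 1, spec90, seed = 2)
  az <- truthSummary(ph90$truth)$azimuthHistogram
  expect_equal(az$fraction[az$lo <= 90 & az$hi > 90], 1)
})
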