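test_that("median filter leaves constants alone and removes impulses", {
  const <- VoxelVolume(array(55, c(16, 16, 16)), 1.8)
  expect_identical(volumeData(medianFilterVolume(const, 1.8)),
                   volumeData(const))
  # single-voxel impulse, 1-voxel ball (7 voxels): median is background
  arr <- array(30, c(16, 16, 16))
  arr[8, 8, 8] <- 200
  vol <- VoxelVolume(arr, 1.8)
  out <- volumeData(medianFilterVolume(vol, 1.8))
  # brute-force median over the 7-voxel ball at the impulse site
  ball <- c(200, rep(30, 6))
  expect_equal(out[8, 8, 8], median(ball))
  expect_true(all(out == 30))
})

test_that("a radius that rounds to zero voxels is the identity", {
  set.seed(3)
  arr <- array(runif(16^3, 0, 255), c(16, 16, 16))
  vol <- VoxelVolume(arr, 1.8)
  expect_identical(volumeData(medianFilterVolume(vol, 0)), arr)
  expect_identical(volumeData(medianFilterVolume(vol, 0.5)), arr)  # < half voxel
  expect_error(medianFilterVolume(vol, -1), ">= 0")
})

test_that("median filtering is idempotent on large piecewise-constant blocks", {
  arr <- array(20, c(24, 24, 24))
  arr[, , 13:24] <- 200  # feature much larger than the 1-voxel ball
  vol <- VoxelVolume(arr, 1)
  once <- medianFilterVolume(vol, 1)
  twice <- medianFilterVolume(once, 1)
  expect_identical(volumeData(once), volumeData(twice))
})

test_that("per-slice filtering matches 2D filtering of each slice", {
  set.seed(4)
  arr <- array(sample(0:255, 16^3, replace = TRUE), c(16, 16, 16))
  vol <- VoxelVolume(arr, 1)
  out <- volumeData(medianFilterVolume(vol, 1, perSlice = TRUE))
  # slice 5 filtered on its own must agree (disc stays in-plane)
  one <- VoxelVolume(array(arr[5, , ], c(1, 16, 16)), 1)
  expect_equal(out[5, , ], volumeData(medianFilterVolume(one, 1,
                                                         perSlice = TRUE))[1, , ])
  # and differ from the full 3D ball result somewhere
  out3d <- volumeData(medianFilterVolume(vol, 1))
  expect_false(identical(out, out3d))
})

test_that("maximum-entropy threshold splits a uniform histogram in half", {
  expect_equal(kapurThreshold(rep(1, 256)), 127)
})

test_that("maximum-entropy threshold equals the exhaustive-scan oracle", {
  h <- c(5, 0, 0, 40, 0, 0, 0, 55)
  expect_equal(kapurThreshold(h), kapurBrute(h))
  # two-Gaussian mixture: threshold strictly between the modes
  set.seed(2)
  x <- pmin(pmax(round(c(rnorm(5e4, 60, 10), rnorm(5e4, 180, 10))), 0), 255)
  h2 <- tabulate(x + 1, 256)
  t2 <- kapurThreshold(h2, 0:255)
  expect_equal(t2, kapurBrute(h2, 0:255))
  expect_gt(t2, 60)
  expect_lt(t2, 180)
  # property: agreement on random histograms
  set.seed(11)
  for (i in 1:30) {
    counts <- rpois(sample(8:64, 1), sample(c(1, 5, 50), 1))
    if (sum(counts > 0) < 2) counts[1:2] <- 1
    expect_equal(kapurThreshold(counts), kapurBrute(counts))
  }
  expect_error(kapurThreshold(c(0, 7, 0)), "two non-empty")
})

test_that("noiseless three-level phantoms segment voxel-exactly", {
  ph <- generateFibers(c(48, 48, 48), 1.8,
                       fiberSpec(4, radius = 6), seed = 31)
  ph <- addParticles(ph$volume, ph$truth, particleSpec(5, volume = 400),
                     seed = 32)
  seg <- segmentPhases(ph$volume)
  arr <- volumeData(ph$volume)
  expect_identical(volumeData(seg$fiber), array(arr == 100, dim(arr)))
  expect_identical(volumeData(seg$particle), array(arr == 220, dim(arr)))
  expect_identical(volumeData(seg$material), array(arr > 30, dim(arr)))
  # masks partition material: disjoint and unioning back
  expect_false(any(volumeData(seg$fiber) & volumeData(seg$particle)))
  expect_identical(volumeData(seg$fiber) | volumeData(seg$particle),
                   volumeData(seg$material))
})

test_that("two-level volumes fall back to material-only segmentation", {
  ph <- generateFibers(c(32, 32, 32), 1.8, fiberSpec(3, radius = 5),
                       seed = 33)
  expect_warning(seg <- segmentPhases(ph$volume), "material-only")
  expect_equal(sum(volumeData(seg$particle)), 0)
  expect_identical(volumeData(seg$fiber), volumeData(seg$material))
  expect_true(is.na(seg$thresholds[["t2"]]))
  # constant volume: no classes at all
  expect_error(segmentPhases(VoxelVolume(array(9, c(8, 8, 8)), 1)),
               "constant")
})

test_that("segmentation stays below 2% voxel error under moderate noise", {
  ph <- generateFibers(c(64, 64, 64), 1.8, fiberSpec(6, radius = 7),
                       seed = 41)
  ph <- addParticles(ph$volume, ph$truth, particleSpec(6, volume = 500),
                     seed = 42)
  clean <- volumeData(ph$volume)
  # noise SD at 15% of the background/fiber class separation (70 levels)
  noisy <- degradeVolume(ph$volume, blurSigma = 0, noiseSd = 0.15 * 70,
                         seed = 43)
  seg <- segmentPhases(medianFilterVolume(noisy, 1.8))
  errMaterial <- mean(volumeData(seg$material) != (clean > 30))
  expect_lt(errMaterial, 0.02)
})

test_that("despeckling removes only sub-threshold components", {
  arr <- array(FALSE, c(32, 32, 32))
  arr[5:20, 5:20, 5:8] <- TRUE      # large slab
  arr[28, 28, 28] <- TRUE           # speck
  m <- asFiberMask(arr)
  out <- removeSmallComponents(m, minVoxels = 50)
  expect_equal(sum(volumeData(out)), 16 * 16 * 4)
  expect_false(volumeData(out)[28, 28, 28])
})
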