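test_that("skeletonizing an empty mask yields an empty skeleton", {
  m <- asFiberMask(array(FALSE, c(8, 8, 8)))
  expect_equal(nrow(skeletonize(m)), 0)
  expect_false(any(skeletonize(m, asMask = TRUE)))
})

test_that("a straight cylinder thins to a single path on its axis", {
  mask <- cylinderMask(c(21, 21, 48), c(1, 0, 0), radiusVox = 4)
  sk <- skeletonize(mask, asMask = TRUE)
  pos <- skeletonize(mask)
  expect_gt(nrow(pos), 30)
  # one 26-connected piece, one voxel wide: component count 1, no tunnels
  expect_equal(labelComponents(sk, 26)$n, 1)
  # all skeleton voxels within one voxel of the true axis (y = z = 10)
  d <- sqrt((pos[, "y"] - 10)^2 + (pos[, "z"] - 10)^2)
  expect_lte(max(d), 1)
  # unit width: each interior voxel has exactly two 26-neighbors
  nbrs <- vapply(seq_len(nrow(pos)), function(i) {
    sum(abs(pos[, 1] - pos[i, 1]) <= 1 & abs(pos[, 2] - pos[i, 2]) <= 1 &
          abs(pos[, 3] - pos[i, 3]) <= 1) - 1L
  }, integer(1))
  expect_true(all(nbrs <= 2))
  expect_equal(sum(nbrs == 1), 2)  # exactly two endpoints
})

test_that("thinning preserves the loop of a solid torus", {
  shape <- c(40, 40, 40)
  g <- expand.grid(z = 0:39, y = 0:39, x = 0:39)
  d2 <- (sqrt((g$x - 20)^2 + (g$y - 20)^2) - 12)^2 + (g$z - 20)^2
  mask <- asFiberMask(array(d2 <= 3.5^2, shape))
  sk <- skeletonize(mask, asMask = TRUE)
  pos <- skeletonize(mask)
  n <- nrow(pos)
  comp <- labelComponents(sk, 26)$n
  # cycle rank = edges - vertices + components must be 1 (one tunnel)
  edges <- 0
  for (a in seq_len(n - 1)) {
    adj <- abs(pos[(a + 1):n, 1] - pos[a, 1]) <= 1 &
      abs(pos[(a + 1):n, 2] - pos[a, 2]) <= 1 &
      abs(pos[(a + 1):n, 3] - pos[a, 3]) <= 1
    edges <- edges + sum(adj)
  }
  expect_equal(comp, 1)
  expect_equal(edges - n + comp, 1)
})

test_that("structure tensor recovers axis-aligned orientations", {
  mx <- cylinderMask(c(32, 32, 48), c(1, 0, 0), 5)
  px <- skeletonize(mx)
  ox <- localOrientation(mx, px, windowUm = 19)
  expect_lt(mean(angDiff(ox$theta[ox$valid], 0)), 2)
  expect_lt(mean(abs(ox$phi[ox$valid] - 90)), 2)
  # along the stack axis: latitude 0, azimuth 0 by convention
  mz <- cylinderMask(c(48, 32, 32), c(0, 0, 1), 5)
  pz <- skeletonize(mz)
  oz <- localOrientation(mz, pz, windowUm = 19)
  expect_lt(mean(abs(oz$phi[oz$valid])), 2)
  expect_true(all(oz$theta[oz$valid] == 0))
})

test_that("orientation output is antipodally invariant", {
  set.seed(5)
  for (i in 1:20) {
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2))
    expect_equal(scaffoldCT:::directionToAngles(v),
                 scaffoldCT:::directionToAngles(-v))
  }
})

test_that("oblique orientation survives blur and noise", {
  vs <- 1.8
  spec <- fiberSpec(1, radius = 5 * vs, orientationMode = "aligned",
                    alignedAzimuth = 45, angularJitter = 0,
                    latitudeRange = c(90, 90))
  errs <- vapply(1:5, function(s) {
    ph <- generateFibers(c(48, 48, 48), vs, spec, seed = 50 + s)
    # SNR 5: class separation 70 gray levels, noise SD 14
    deg <- degradeVolume(ph$volume, blurSigma = vs, noiseSd = 14,
                         seed = 60 + s)
    seg <- segmentPhases(medianFilterVolume(deg, vs), stages = 1)
    fiber <- removeSmallComponents(seg$fiber)
    pos <- skeletonize(fiber)
    ori <- localOrientation(fiber, pos)
    mean(angDiff(ori$theta[ori$valid], 45))
  }, numeric(1))
  expect_lt(mean(errs), 5)
})

test_that("constant windows are flagged invalid", {
  m <- asFiberMask(array(TRUE, c(32, 32, 32)))  # no gradient anywhere
  o <- localOrientation(m, matrix(c(16L, 16L, 16L), 1), windowUm = 9)
  expect_false(o$valid)
  expect_true(is.na(o$theta))
})

test_that("ray-cast diameters match the cylinder geometry", {
  vs <- 1.8
  mask <- cylinderMask(c(33, 33, 48), c(1, 0, 0), 5, voxelSize = vs)
  pos <- skeletonize(mask)
  mid <- pos[abs(pos[, "x"] - 24) < 8, , drop = FALSE]
  rho <- matrix(rep(c(1, 0, 0), each = nrow(mid)), ncol = 3)
  d <- diameterAtPoint(mask, mid, rho)
  expect_lt(abs(median(d) - 18), vs)  # 10-voxel diameter, within 1 voxel
  # oblique cylinder: orthogonal measurement, not the elongated axial chord
  dir <- c(1, 1, 0) / sqrt(2)
  mo <- cylinderMask(c(25, 49, 49), dir, 5, voxelSize = vs)
  po <- skeletonize(mo)
  ctr <- po[abs(po[, "y"] - 24) < 10 & abs(po[, "x"] - 24) < 10, ,
            drop = FALSE]
  ro <- matrix(rep(dir, each = nrow(ctr)), ncol = 3)
  do <- diameterAtPoint(mo, ctr, ro)
  expect_lt(abs(median(do) - 18), vs)
  # a point outside the mask is invalid
  out <- diameterAtPoint(mask, c(0L, 0L, 0L), c(1, 0, 0))
  expect_true(is.na(out))
})

test_that("orientation histograms bin, normalize and conserve counts", {
  pts <- data.frame(theta = rep(45, 7), phi = rep(88, 7),
                    valid = rep(TRUE, 7))
  az <- orientationHistogram(pts, "azimuth", 10)
  expect_equal(sum(az$count), 7)
  expect_equal(az$fraction[az$lo == 40], 1)
  lat <- orientationHistogram(pts, "latitude", 10)
  expect_equal(lat$fraction[lat$lo == 80], 1)
  expect_error(orientationHistogram(pts, "azimuth", 7), "divide")
  # invariant to point ordering
  set.seed(8)
  pts2 <- data.frame(theta = runif(100, 0, 180), phi = runif(100, 0, 90),
                     valid = TRUE)
  perm <- pts2[sample.int(100), ]
  expect_equal(orientationHistogram(pts2, "azimuth"),
               orientationHistogram(perm, "azimuth"))
  # latitude of 90 degrees lands in the closed top bin
  top <- data.frame(theta = 0, phi = 90, valid = TRUE)
  lt <- orientationHistogram(top, "latitude", 10)
  expect_equal(lt$count[lt$hi == 90], 1)
})

test_that("isotropic directions give sin-weighted latitude occupancy", {
  set.seed(13)
  v <- matrix(rnorm(3e4), ncol = 3)
  ang <- t(apply(v, 1, scaffoldCT:::directionToAngles))
  pts <- data.frame(theta = ang[, 1], phi = ang[, 2], valid = TRUE)
  lat <- orientationHistogram(pts, "latitude", 15)
  # band solid angle between colatitudes: cos(lo) - cos(hi)
  w <- cos(lat$lo * pi / 180) - cos(lat$hi * pi / 180)
  expect_equal(lat$fraction, w / sum(w), tolerance = 0.05)
})

test_that("diameter distributions use half-open micron bins", {
  pts <- data.frame(diameter = c(2, 3, 12), valid = TRUE)
  d <- diameterDistribution(pts)
  expect_equal(d$count, c(2, 0, 1, 0, 0, 0))
  expect_equal(sum(d$percentage), 100)
  # fixed 18 µm fibers all fall in the 10-25 µm class
  ph <- generateFibers(c(48, 48, 48), 1.8, fiberSpec(3, radius = 9),
                       seed = 71)
  seg <- segmentPhases(ph$volume, stages = 1)
  pts2 <- analyzeFibers(seg$fiber)
  dd <- diameterDistribution(pts2)
  expect_equal(dd$percentage[dd$lo == 10], 100)
  expect_error(diameterDistribution(pts, binEdges = c(5, 5, 10)),
               "increasing")
})
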