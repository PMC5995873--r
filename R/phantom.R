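#' Construct a fiber population specification
#'
#' Convenience constructor for [FiberSpec-class]. Radii are drawn from a
#' fixed, uniform or lognormal distribution (µm). Orientation is either
#' `"random"` (azimuth uniform on \[0,180)) or `"aligned"` (wrapped normal
#' around `alignedAzimuth` with SD `angularJitter`). Latitude is uniform in
#' `latitudeRange`; the default 50–90° band keeps fibers close to the slice
#' plane, as layer-by-layer electrospun deposition does.
#'
#' @param nFibers number of fibers.
#' @param radius either a single number (fixed radius, µm) or a list such as
#'   `list(kind = "uniform", min = 3, max = 10)` or
#'   `list(kind = "lognormal", meanlog = 2, sdlog = 0.3)`.
#' @param orientationMode `"random"` or `"aligned"`.
#' @param alignedAzimuth preferred azimuth in degrees, \[0,180).
#' @param angularJitter wrapped-normal SD (degrees) of azimuth about
#'   `alignedAzimuth` (aligned mode only).
#' @param latitudeRange numeric(2) degrees within \[0,90\]; 90° = in-plane.
#' @param intensity fiber gray level (8-bit scale by default).
#' @return a [FiberSpec-class] object.
#' @examples
#' fiberSpec(20, radius = 9, orientationMode = "aligned", alignedAzimuth = 45)
#' @export
fiberSpec <- function(nFibers, radius = 9,
                      orientationMode = c("random", "aligned"),
                      alignedAzimuth = 90, angularJitter = 5,
                      latitudeRange = c(50, 90), intensity = 100) {
  orientationMode <- match.arg(orientationMode)
  if (is.numeric(radius) && length(radius) == 1L)
    radius <- list(kind = "fixed", value = radius)
  params <- unlist(radius[setdiff(names(radius), "kind")])
  new("FiberSpec", nFibers = as.integer(nFibers),
      radiusKind = radius$kind, radiusParams = params,
      orientationMode = orientationMode,
      alignedAzimuth = as.numeric(alignedAzimuth),
      angularJitter = as.numeric(angularJitter),
      latitudeRange = as.numeric(latitudeRange),
      intensity = as.numeric(intensity))
}

#' Construct a particle population specification
#'
#' Convenience constructor for [ParticleSpec-class]. Particle volumes (µm³)
#' follow a fixed, uniform or lognormal distribution. With probability
#' `clustering`, each new particle is seeded touching a previously placed
#' one and joins its aggregate, emulating agglomeration of ceramic
#' microparticles; otherwise it starts a new aggregate.
#'
#' @param nParticles number of particles.
#' @param volume single number (fixed volume, µm³) or a distribution list as
#'   in [fiberSpec()].
#' @param clustering probability in \[0,1\] of seeding adjacent to an
#'   existing particle.
#' @param intensity particle gray level; must exceed the fiber level (the
#'   ceramic phase absorbs most strongly).
#' @return a [ParticleSpec-class] object.
#' @examples
#' particleSpec(10, volume = list(kind = "uniform", min = 50, max = 500))
#' @export
particleSpec <- function(nParticles, volume = 200, clustering = 0.3,
                         intensity = 220) {
  if (is.numeric(volume) && length(volume) == 1L)
    volume <- list(kind = "fixed", value = volume)
  params <- unlist(volume[setdiff(names(volume), "kind")])
  new("ParticleSpec", nParticles = as.integer(nParticles),
      volumeKind = volume$kind, volumeParams = params,
      clustering = as.numeric(clustering), intensity = as.numeric(intensity))
}

# sample fiber angles; returns data.frame(theta, phi) in degrees
sampleFiberAngles <- function(spec) {
  n <- spec@nFibers
  theta <- if (spec@orientationMode == "random") {
    stats::runif(n, 0, 180)
  } else {
    (spec@alignedAzimuth + stats::rnorm(n, 0, spec@angularJitter)) %% 180
  }
  phi <- stats::runif(n, spec@latitudeRange[1], spec@latitudeRange[2])
  data.frame(theta = theta, phi = phi)
}

# (theta, phi) degrees -> unit direction (x, y, z); phi is measured from
# the stack (z) axis so phi = 90 is in-plane
anglesToDirection <- function(theta, phi) {
  t <- theta * pi / 180
  p <- phi * pi / 180
  cbind(x = sin(p) * cos(t), y = sin(p) * sin(t), z = cos(p))
}

# fold a direction to the z >= 0 hemisphere and convert to (theta, phi)
directionToAngles <- function(v) {
  v <- v / sqrt(sum(v^2))
  if (v[3] < 0) v <- -v
  phi <- acos(min(1, max(-1, v[3]))) * 180 / pi
  inplane <- sqrt(v[1]^2 + v[2]^2)
  theta <- if (inplane < 1e-12) 0 else (atan2(v[2], v[1]) * 180 / pi) %% 180
  c(theta = theta, phi = phi)
}

#' Generate a synthetic fibrous phantom with exact ground truth
#'
#' Rasterizes `nFibers` straight solid cylinders spanning a voxel grid. A
#' voxel belongs to a fiber iff its center lies within the fiber radius of
#' the fiber axis; overlapping fibers are counted once. The returned
#' grayscale volume has two levels (background, fiber); pass it through
#' [addParticles()] and [degradeVolume()] for the full imaging model.
#' Identical `(spec, seed)` reproduce the volume bit-for-bit.
#'
#' @param shape integer(3) voxel counts `(nz, ny, nx)`, each >= 32.
#' @param voxelSize voxel edge length in µm (> 0).
#' @param spec a [FiberSpec-class].
#' @param seed integer RNG seed.
#' @param background background gray level (default 30 on an 8-bit scale).
#' @return a list with elements `volume` ([VoxelVolume-class]) and `truth`
#'   ([PhantomTruth-class]).
#' @examples
#' ph <- generateFibers(c(32, 32, 32), 1.8, fiberSpec(3, radius = 5), seed = 1)
#' ph$truth
#' @export
generateFibers <- function(shape, voxelSize, spec, seed, background = 30) {
  stopifnot(is(spec, "FiberSpec"))
  validObject(spec)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("shape must give three axes of at least 32 voxels")
  if (!is.numeric(voxelSize) || voxelSize <= 0)
    stop("voxelSize must be positive (µm)")
  if (spec@intensity <= background)
    stop("fiber intensity must exceed the background level")

  res <- withSeed(seed, {
    n <- spec@nFibers
    radii <- drawDistribution(n, spec@radiusKind, spec@radiusParams)
    if (any(radii / voxelSize < 1))
      stop("fiber radius below one voxel (", voxelSize,
           " µm): unresolvable fiber; increase radius or resolution")
    ang <- sampleFiberAngles(spec)
    dirs <- anglesToDirection(ang$theta, ang$phi)
    anchors <- cbind(z = stats::runif(n, 0, shape[1] - 1),
                     y = stats::runif(n, 0, shape[2] - 1),
                     x = stats::runif(n, 0, shape[3] - 1))
    phase <- array(0L, shape)
    for (f in seq_len(n)) {
      .rasterCylinder(phase, shape, anchors[f, "x"], anchors[f, "y"],
                      anchors[f, "z"], dirs[f, "x"], dirs[f, "y"],
                      dirs[f, "z"], radii[f] / voxelSize, 1L)
    }
    fibers <- if (n > 0) data.frame(
      anchorZ = anchors[, "z"], anchorY = anchors[, "y"],
      anchorX = anchors[, "x"], dirX = dirs[, "x"], dirY = dirs[, "y"],
      dirZ = dirs[, "z"], radius = radii, theta = ang$theta, phi = ang$phi
    ) else data.frame()
    list(phase = phase, fibers = fibers)
  })

  vol <- array(background, dim = shape)
  vol[res$phase == 1L] <- spec@intensity
  truth <- new("PhantomTruth", fibers = res$fibers,
               particles = data.frame(), aggregates = data.frame(),
               intensityLevels = c(background = background,
                                   fiber = spec@intensity, particle = NA_real_),
               materialVoxels = c(fiber = sum(res$phase == 1L), particle = 0),
               shape = shape, voxelSize = as.numeric(voxelSize),
               seed = as.integer(seed))
  volume <- new("VoxelVolume", data = vol, voxelSize = as.numeric(voxelSize),
                provenance = sprintf(
                  "phantom: %d fibers, %s orientation, seed %d",
                  spec@nFibers, spec@orientationMode, as.integer(seed)))
  list(volume = volume, truth = truth)
}

#' Embed spherical particle aggregates into a phantom
#'
#' Rasterizes spheres at the particle gray level, overwriting fiber voxels
#' where they overlap (particles sit embedded in fibers). With probability
#' `clustering` a particle is seeded touching an existing one, inheriting
#' its aggregate id; aggregates therefore form connected clumps. Particles
#' whose analytic volume falls below one voxel are still recorded in the
#' truth but flagged sub-resolution (they may rasterize to zero voxels and
#' are invisible to segmentation). Exact per-aggregate voxel counts are
#' stored in the truth.
#'
#' @param volume a [VoxelVolume-class] from [generateFibers()] (or a
#'   fiber-free phantom).
#' @param truth the matching [PhantomTruth-class].
#' @param spec a [ParticleSpec-class].
#' @param seed integer RNG seed.
#' @return list(volume, truth), updated.
#' @examples
#' ph <- generateFibers(c(32, 32, 32), 1.8, fiberSpec(2, radius = 5), seed = 1)
#' ph <- addParticles(ph$volume, ph$truth, particleSpec(5, volume = 300), seed = 2)
#' ph$truth
#' @export
addParticles <- function(volume, truth, spec, seed) {
  stopifnot(is(volume, "VoxelVolume"), is(truth, "PhantomTruth"),
            is(spec, "ParticleSpec"))
  validObject(spec)
  if (nrow(truth@particles) > 0)
    stop("volume already contains particles; start from a fiber phantom")
  lev <- truth@intensityLevels
  if (spec@intensity <= lev[["fiber"]])
    stop("particle intensity must exceed the fiber level")
  vs <- truth@voxelSize
  shape <- truth@shape
  vol <- volumeData(volume)
  # reconstruct the noiseless phase grid from the intensity levels
  phase <- array(0L, shape)
  phase[vol == lev[["fiber"]]] <- 1L
  agg <- array(0L, shape)

  res <- withSeed(seed, if (spec@nParticles == 0L) {
    list(particles = data.frame(), phase = phase, agg = agg)
  } else {
    n <- spec@nParticles
    vols <- drawDistribution(n, spec@volumeKind, spec@volumeParams)
    radii <- (3 * vols / (4 * pi))^(1 / 3)          # µm
    rvox <- radii / vs
    centers <- matrix(NA_real_, n, 3,
                      dimnames = list(NULL, c("z", "y", "x")))
    aggId <- integer(n)
    nextAgg <- 0L
    for (p in seq_len(n)) {
      clustered <- p > 1L && stats::runif(1) < spec@clustering
      if (clustered) {
        q <- sample.int(p - 1L, 1L)
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        d <- 0.8 * (rvox[q] + rvox[p])      # slight overlap: touching spheres
        ctr <- centers[q, ] + u * d
        ctr <- pmin(pmax(ctr, 0), shape - 1)
        aggId[p] <- aggId[q]
      } else {
        ctr <- c(stats::runif(1, 0, shape[1] - 1),
                 stats::runif(1, 0, shape[2] - 1),
                 stats::runif(1, 0, shape[3] - 1))
        nextAgg <- nextAgg + 1L
        aggId[p] <- nextAgg
      }
      centers[p, ] <- ctr
      .rasterSphere(phase, agg, shape, ctr[3], ctr[2], ctr[1], rvox[p],
                    2L, aggId[p])
    }
    particles <- data.frame(
      centerZ = centers[, "z"], centerY = centers[, "y"],
      centerX = centers[, "x"], radius = radii, volume = vols,
      aggregate = aggId, subResolution = vols < vs^3)
    list(particles = particles, phase = phase, agg = agg)
  })

  aggCounts <- if (any(res$agg > 0L)) {
    tb <- table(res$agg[res$agg > 0L])
    data.frame(aggregate = as.integer(names(tb)),
               voxelCount = as.integer(tb))
  } else data.frame()

  out <- array(lev[["background"]], dim = shape)
  out[res$phase == 1L] <- lev[["fiber"]]
  out[res$phase == 2L] <- spec@intensity
  newTruth <- new("PhantomTruth", fibers = truth@fibers,
                  particles = res$particles, aggregates = aggCounts,
                  intensityLevels = c(background = lev[["background"]],
                                      fiber = lev[["fiber"]],
                                      particle = spec@intensity),
                  materialVoxels = c(fiber = sum(res$phase == 1L),
                                     particle = sum(res$phase == 2L)),
                  shape = shape, voxelSize = vs, seed = truth@seed)
  newVol <- new("VoxelVolume", data = out, voxelSize = vs,
                provenance = c(provenance(volume), sprintf(
                  "particles: %d spheres, clustering %.2f, seed %d",
                  spec@nParticles, spec@clustering, as.integer(seed))))
  list(volume = newVol, truth = newTruth)
}

#' Degrade a phantom with blur and noise
#'
#' Applies a normalized separable Gaussian blur (sigma in µm) followed by
#' additive zero-mean Gaussian noise, clipped to the valid grayscale range.
#' Emulates detector point spread and photon noise well enough for
#' robustness tests of the analysis chain; it is not a physical projection
#' simulation. Deterministic under a fixed seed.
#'
#' @param volume a [VoxelVolume-class].
#' @param blurSigma Gaussian blur SD in µm (>= 0; 0 disables).
#' @param noiseSd additive noise SD in gray levels (>= 0; 0 disables).
#' @param seed integer RNG seed for the noise.
#' @param clipRange numeric(2) valid grayscale range (default 0–255).
#' @return a degraded [VoxelVolume-class].
#' @examples
#' ph <- generateFibers(c(32, 32, 32), 1.8, fiberSpec(2, radius = 5), seed = 1)
#' noisy <- degradeVolume(ph$volume, blurSigma = 1.8, noiseSd = 10, seed = 3)
#' @export
degradeVolume <- function(volume, blurSigma, noiseSd, seed,
                          clipRange = c(0, 255)) {
  stopifnot(is(volume, "VoxelVolume"))
  if (blurSigma < 0 || noiseSd < 0)
    stop("blurSigma and noiseSd must be >= 0")
  arr <- volumeData(volume)
  if (blurSigma > 0)
    arr <- gaussSmooth3D(arr, blurSigma / voxelSize(volume))
  if (noiseSd > 0) {
    arr <- arr + withSeed(seed, array(stats::rnorm(length(arr), 0, noiseSd),
                                      dim = dim(arr)))
  }
  arr[arr < clipRange[1]] <- clipRange[1]
  arr[arr > clipRange[2]] <- clipRange[2]
  new("VoxelVolume", data = arr, voxelSize = voxelSize(volume),
      provenance = c(provenance(volume),
                     sprintf("degrade: blur %.3g µm, noise SD %.3g, seed %d",
                             blurSigma, noiseSd, as.integer(seed))))
}

# length of the intersection of the line (anchor, dir) with the physical
# box [-1/2, n-1/2]^3, in voxel units
lineBoxLength <- function(anchor, dir, shape) {
  tmin <- -Inf; tmax <- Inf
  lo <- rep(-0.5, 3); hi <- shape - 0.5
  for (ax in 1:3) {
    if (abs(dir[ax]) < 1e-12) {
      if (anchor[ax] < lo[ax] || anchor[ax] > hi[ax]) return(0)
    } else {
      t1 <- (lo[ax] - anchor[ax]) / dir[ax]
      t2 <- (hi[ax] - anchor[ax]) / dir[ax]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  max(0, tmax - tmin)
}

#' Analytic reference tables from phantom ground truth
#'
#' Computes, from the generative truth alone (never from the rasterized
#' volume), the quantities the analysis chain is expected to recover:
#' azimuth/latitude orientation histograms, the fiber diameter
#' distribution, the particle size distribution, and porosity. Porosity is
#' given three ways: exact (from the rasterized material voxel counts),
#' analytic (cylinder/sphere volumes, overlaps ignored), and an attached
#' discretization bound — the surface-voxel budget within which analytic
#' and rasterized volumes must agree.
#'
#' @param truth a [PhantomTruth-class].
#' @param azimuthBinWidth,latitudeBinWidth histogram bin widths (degrees).
#' @param diameterEdges fiber-diameter bin edges (µm).
#' @param volumeEdges particle-volume bin edges (µm³).
#' @return list with `azimuthHistogram`, `latitudeHistogram`,
#'   `diameterDistribution`, `particleSizes`, `porosity` (list: `exact`,
#'   `analytic`, `discretizationBound`, percentages).
#' @export
truthSummary <- function(truth, azimuthBinWidth = 10, latitudeBinWidth = 10,
                         diameterEdges = c(1, 5, 10, 25, 35, 45, 75),
                         volumeEdges = c(5.83, 1000, 1e6)) {
  stopifnot(is(truth, "PhantomTruth"))
  if (nrow(truth@fibers) == 0 && nrow(truth@particles) == 0)
    stop("empty truth: nothing to summarize")
  fb <- truth@fibers
  vs <- truth@voxelSize
  total <- prod(truth@shape)

  az <- binAngles(fb$theta, 0, 180, azimuthBinWidth, "azimuth")
  lat <- binAngles(fb$phi, 0, 90, latitudeBinWidth, "latitude")
  dia <- binSizes(2 * fb$radius, diameterEdges, "µm")
  psz <- if (nrow(truth@particles) > 0)
    binSizes(truth@particles$volume, volumeEdges, "µm³")
  else data.frame()

  # analytic material volume in voxel units (overlaps ignored)
  cylVox <- 0; surfVox <- 0
  if (nrow(fb) > 0) {
    for (f in seq_len(nrow(fb))) {
      rv <- fb$radius[f] / vs
      L <- lineBoxLength(c(fb$anchorZ[f], fb$anchorY[f], fb$anchorX[f]),
                         c(fb$dirZ[f], fb$dirY[f], fb$dirX[f]), truth@shape)
      cylVox <- cylVox + pi * rv^2 * L
      surfVox <- surfVox + 2 * pi * rv * L + 2 * pi * rv^2
    }
  }
  if (nrow(truth@particles) > 0) {
    rv <- truth@particles$radius / vs
    cylVox <- cylVox + sum(4 / 3 * pi * rv^3)
    surfVox <- surfVox + sum(4 * pi * rv^2)
  }
  exactFrac <- sum(truth@materialVoxels) / total
  list(
    azimuthHistogram = az, latitudeHistogram = lat,
    diameterDistribution = dia, particleSizes = psz,
    porosity = list(
      exact = 100 * (1 - exactFrac),
      analytic = 100 * (1 - min(1, cylVox / total)),
      discretizationBound = 100 * surfVox / total
    )
  )
}

# shared binning helpers (half-open bins, last bin closed)
binAngles <- function(values, lo, hi, width, axis) {
  edges <- seq(lo, hi, by = width)
  counts <- tabulateBins(values, edges, closeLast = TRUE)
  data.frame(axis = axis, lo = edges[-length(edges)], hi = edges[-1],
             count = counts,
             fraction = if (sum(counts) > 0) counts / sum(counts) else 0)
}

binSizes <- function(values, edges, unit) {
  counts <- tabulateBins(values, edges, closeLast = FALSE)
  data.frame(lo = edges[-length(edges)], hi = edges[-1], unit = unit,
             count = counts,
             percentage = if (sum(counts) > 0) 100 * counts / sum(counts)
                          else 0)
}

tabulateBins <- function(values, edges, closeLast = FALSE) {
  nb <- length(edges) - 1L
  counts <- integer(nb)
  for (b in seq_len(nb)) {
    inBin <- values >= edges[b] & values < edges[b + 1]
    if (closeLast && b == nb)
      inBin <- inBin | values == edges[b + 1]
    counts[b] <- sum(inBin, na.rm = TRUE)
  }
  counts
}
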