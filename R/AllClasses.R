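#' @import methods
NULL

#' VoxelVolume: a 3D grayscale volume with isotropic physical calibration
#'
#' Container for a reconstructed micro-CT volume (or a synthetic phantom).
#' The grid is stored as a numeric 3D array in `(z, y, x)` order, where
#' axis 1 (`z`) is the slice-stacking axis; the physical voxel edge length
#' is isotropic and given in micrometres.
#'
#' @slot data numeric 3D array, dimensions `(nz, ny, nx)`.
#' @slot voxelSize numeric(1), voxel edge length in µm (> 0).
#' @slot provenance character vector of processing-log entries.
#'
#' @seealso [readVolume()], [extractROI()], [generateFibers()]
#' @export
setClass("VoxelVolume",
  representation(data = "array", voxelSize = "numeric",
                 provenance = "character"),
  prototype(voxelSize = 1, provenance = character())
)

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array (z, y, x)")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a single positive number (µm)")
  if (length(msg)) msg else TRUE
})

#' PhaseMask: a binary mask for one material phase
#'
#' Labels one phase of a segmented volume — `"material"` (fiber or
#' particle), `"fiber"` or `"particle"` — on the same grid as its source
#' volume. Fiber and particle masks from one segmentation are disjoint and
#' union to the material mask.
#'
#' @slot data logical 3D array `(nz, ny, nx)`.
#' @slot phase character(1): `"material"`, `"fiber"` or `"particle"`.
#' @slot voxelSize numeric(1), µm.
#' @slot provenance character vector.
#'
#' @seealso [segmentPhases()], [porosity()], [labelComponents()]
#' @export
setClass("PhaseMask",
  representation(data = "array", phase = "character", voxelSize = "numeric",
                 provenance = "character"),
  prototype(phase = "material", voxelSize = 1, provenance = character())
)

setValidity("PhaseMask", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L || !is.logical(object@data))
    msg <- c(msg, "data must be a logical 3D array")
  if (!object@phase %in% c("material", "fiber", "particle"))
    msg <- c(msg, "phase must be 'material', 'fiber' or 'particle'")
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a single positive number (µm)")
  if (length(msg)) msg else TRUE
})

#' FiberSpec: generative parameters for phantom fibers
#'
#' Describes a population of straight cylindrical fibers: how many, the
#' radius distribution (µm), the orientation model (uniform-random azimuth
#' or concentrated around a preferred azimuth with wrapped-normal jitter),
#' the latitude band, and the fiber gray level.
#'
#' @slot nFibers integer(1), number of fibers.
#' @slot radiusKind `"fixed"`, `"uniform"` or `"lognormal"`.
#' @slot radiusParams named numeric: `value` (fixed); `min`,`max` (uniform);
#'   `meanlog`,`sdlog` (lognormal). All in µm.
#' @slot orientationMode `"random"` (azimuth uniform on \[0,180)) or
#'   `"aligned"` (wrapped normal around `alignedAzimuth`).
#' @slot alignedAzimuth numeric(1), degrees in \[0,180).
#' @slot angularJitter numeric(1) >= 0, wrapped-normal SD in degrees.
#' @slot latitudeRange numeric(2) within \[0,90\]; in-plane fibers have
#'   latitude 90°.
#' @slot intensity numeric(1) fiber gray level (must exceed background).
#'
#' @seealso [fiberSpec()], [generateFibers()]
#' @export
setClass("FiberSpec",
  representation(nFibers = "integer", radiusKind = "character",
                 radiusParams = "numeric", orientationMode = "character",
                 alignedAzimuth = "numeric", angularJitter = "numeric",
                 latitudeRange = "numeric", intensity = "numeric")
)

setValidity("FiberSpec", function(object) {
  msg <- character()
  if (object@nFibers < 0L) msg <- c(msg, "nFibers must be >= 0")
  if (!object@radiusKind %in% c("fixed", "uniform", "lognormal"))
    msg <- c(msg, "radiusKind must be 'fixed', 'uniform' or 'lognormal'")
  if (object@radiusKind == "fixed" && object@radiusParams[["value"]] <= 0)
    msg <- c(msg, "fiber radius must be > 0")
  if (object@radiusKind == "uniform" &&
      (object@radiusParams[["min"]] <= 0 ||
       object@radiusParams[["max"]] < object@radiusParams[["min"]]))
    msg <- c(msg, "uniform radius range must satisfy 0 < min <= max")
  if (!object@orientationMode %in% c("random", "aligned"))
    msg <- c(msg, "orientationMode must be 'random' or 'aligned'")
  if (object@alignedAzimuth < 0 || object@alignedAzimuth >= 180)
    msg <- c(msg, "alignedAzimuth must lie in [0, 180)")
  if (object@angularJitter < 0) msg <- c(msg, "angularJitter must be >= 0")
  lr <- object@latitudeRange
  if (length(lr) != 2L || lr[1] < 0 || lr[2] > 90 || lr[1] > lr[2])
    msg <- c(msg, "latitudeRange must be an interval within [0, 90]")
  if (length(msg)) msg else TRUE
})

#' ParticleSpec: generative parameters for phantom particle aggregates
#'
#' Describes spherical ceramic particles: the count, the volume
#' distribution (µm³), a clustering probability (chance that a particle is
#' seeded touching an existing one, forming an aggregate), and the particle
#' gray level, which must exceed the fiber level (the ceramic phase is the
#' strong absorber).
#'
#' @slot nParticles integer(1).
#' @slot volumeKind `"fixed"`, `"uniform"` or `"lognormal"`.
#' @slot volumeParams named numeric (µm³), as for [fiberSpec()] radii.
#' @slot clustering numeric(1) in \[0,1\].
#' @slot intensity numeric(1) particle gray level.
#'
#' @seealso [particleSpec()], [addParticles()]
#' @export
setClass("ParticleSpec",
  representation(nParticles = "integer", volumeKind = "character",
                 volumeParams = "numeric", clustering = "numeric",
                 intensity = "numeric")
)

setValidity("ParticleSpec", function(object) {
  msg <- character()
  if (object@nParticles < 0L) msg <- c(msg, "nParticles must be >= 0")
  if (!object@volumeKind %in% c("fixed", "uniform", "lognormal"))
    msg <- c(msg, "volumeKind must be 'fixed', 'uniform' or 'lognormal'")
  if (object@volumeKind == "fixed" && object@volumeParams[["value"]] <= 0)
    msg <- c(msg, "particle volume must be > 0")
  if (object@clustering < 0 || object@clustering > 1)
    msg <- c(msg, "clustering must be a probability in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: exact generative ground truth of a synthetic phantom
#'
#' Records everything needed to score a recovery experiment: every fiber
#' (anchor, unit direction, radius, azimuth/latitude), every particle
#' (center, radius, analytic volume, aggregate membership, sub-resolution
#' flag), the exact per-aggregate rasterized voxel counts, the three gray
#' levels, the exact per-phase material voxel counts of the noiseless
#' rasterization, and the generator seed.
#'
#' @slot fibers data.frame: `anchorZ/Y/X` (voxel), `dirX/Y/Z` (unit),
#'   `radius` (µm), `theta`, `phi` (degrees).
#' @slot particles data.frame: `centerZ/Y/X` (voxel), `radius` (µm),
#'   `volume` (µm³, analytic), `aggregate` (id), `subResolution` (logical).
#' @slot aggregates data.frame: `aggregate`, `voxelCount` (exact).
#' @slot intensityLevels named numeric: `background`, `fiber`, `particle`.
#' @slot materialVoxels named numeric: `fiber`, `particle` exact counts in
#'   the noiseless volume.
#' @slot shape integer(3) `(nz, ny, nx)`.
#' @slot voxelSize numeric(1) µm.
#' @slot seed integer(1).
#'
#' @seealso [generateFibers()], [addParticles()], [truthSummary()]
#' @export
setClass("PhantomTruth",
  representation(fibers = "data.frame", particles = "data.frame",
                 aggregates = "data.frame", intensityLevels = "numeric",
                 materialVoxels = "numeric", shape = "integer",
                 voxelSize = "numeric", seed = "integer")
)

setValidity("PhantomTruth", function(object) {
  msg <- character()
  if (nrow(object@fibers) > 0) {
    nrm <- sqrt(object@fibers$dirX^2 + object@fibers$dirY^2 +
                object@fibers$dirZ^2)
    if (any(abs(nrm - 1) > 1e-9))
      msg <- c(msg, "fiber directions must be unit vectors (|rho| = 1)")
  }
  if (length(object@shape) != 3L || any(object@shape <= 0L))
    msg <- c(msg, "shape must be three positive voxel counts")
  if (length(msg)) msg else TRUE
})
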