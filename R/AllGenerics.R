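#' Accessors for volumes and masks
#'
#' `volumeData()` returns the raw 3D array; `voxelSize()` the isotropic
#' voxel edge length in µm; `provenance()` the processing log.
#'
#' @param x a [VoxelVolume-class] or [PhaseMask-class].
#' @return `volumeData`: a 3D array; `voxelSize`: numeric(1) µm;
#'   `provenance`: character vector.
#' @examples
#' vol <- VoxelVolume(array(0, c(4, 4, 4)), voxelSize = 1.8)
#' voxelSize(vol)
#' dim(volumeData(vol))
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @rdname volumeData
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname volumeData
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname volumeData
setMethod("volumeData", "VoxelVolume", function(x) x@data)
#' @rdname volumeData
setMethod("volumeData", "PhaseMask", function(x) x@data)
#' @rdname volumeData
setMethod("voxelSize", "VoxelVolume", function(x) x@voxelSize)
#' @rdname volumeData
setMethod("voxelSize", "PhaseMask", function(x) x@voxelSize)
#' @rdname volumeData
setMethod("provenance", "VoxelVolume", function(x) x@provenance)
#' @rdname volumeData
setMethod("provenance", "PhaseMask", function(x) x@provenance)

#' @describeIn volumeData the phase labeled by a mask
#' @export
setGeneric("maskPhase", function(x) standardGeneric("maskPhase"))
#' @rdname volumeData
setMethod("maskPhase", "PhaseMask", function(x) x@phase)

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume: %d x %d x %d voxels (z,y,x) at %.4g µm/voxel\n",
              d[1], d[2], d[3], object@voxelSize))
  cat(sprintf("  physical extent: %.4g x %.4g x %.4g µm\n",
              d[1] * object@voxelSize, d[2] * object@voxelSize,
              d[3] * object@voxelSize))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " | "), "\n")
})

setMethod("show", "PhaseMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("PhaseMask (%s): %d x %d x %d voxels at %.4g µm/voxel\n",
              object@phase, d[1], d[2], d[3], object@voxelSize))
  cat(sprintf("  %d / %d voxels in phase (%.2f%%)\n", sum(object@data),
              length(object@data), 100 * mean(object@data)))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %d fibers, %d particles in %d aggregates\n",
              nrow(object@fibers), nrow(object@particles),
              nrow(object@aggregates)))
  cat(sprintf("  shape %s at %.4g µm/voxel, seed %d\n",
              paste(object@shape, collapse = " x "), object@voxelSize,
              object@seed))
  mv <- object@materialVoxels
  cat(sprintf("  material voxels: fiber %d, particle %d\n",
              as.integer(mv[["fiber"]]), as.integer(mv[["particle"]])))
})

setMethod("show", "FiberSpec", function(object) {
  cat(sprintf("FiberSpec: %d fibers, %s radius, %s orientation\n",
              object@nFibers, object@radiusKind, object@orientationMode))
})

setMethod("show", "ParticleSpec", function(object) {
  cat(sprintf("ParticleSpec: %d particles, %s volume, clustering %.2f\n",
              object@nParticles, object@volumeKind, object@clustering))
})
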