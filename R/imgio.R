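#' Create a VoxelVolume from an array
#'
#' @param data numeric 3D array in `(z, y, x)` order.
#' @param voxelSize isotropic voxel edge length in µm.
#' @param provenance optional character log entries.
#' @return a [VoxelVolume-class].
#' @examples
#' VoxelVolume(array(0, c(8, 8, 8)), voxelSize = 1.8)
#' @export
VoxelVolume <- function(data, voxelSize, provenance = character()) {
  new("VoxelVolume", data = data, voxelSize = as.numeric(voxelSize),
      provenance = provenance)
}

#' Read a volume from a multi-page TIFF or a directory of slices
#'
#' Slices are stacked along axis 1 (z). For a directory, files are read in
#' lexicographic order and must share one slice shape; grayscale is
#' preserved losslessly for 8- and 16-bit integer data. The voxel size is
#' required metadata: TIFF resolution tags are deliberately not trusted
#' (dialects vary), so physical calibration always comes from the caller
#' or a config file.
#'
#' @param path multi-page TIFF file or directory of single-slice TIFFs.
#' @param voxelSize isotropic voxel size in µm.
#' @return a [VoxelVolume-class].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, voxelSize) {
  if (missing(voxelSize))
    stop("voxelSize (µm) is required; it is not read from TIFF tags")
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0) stop("no TIFF slices found in ", path)
    slices <- lapply(files, function(f) asIntensity(tiff::readTIFF(f,
                                                     as.is = TRUE)))
    shapes <- vapply(slices, dim, integer(2))
    if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
      stop("slice shape mismatch at ",
           basename(files[which(shapes[1, ] != shapes[1, 1] |
                                shapes[2, ] != shapes[2, 1])[1]]))
  } else if (file.exists(path)) {
    slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    slices <- lapply(slices, asIntensity)
  } else stop("cannot read volume: ", path, " does not exist")
  nz <- length(slices)
  arr <- array(0, c(nz, dim(slices[[1]])))
  for (i in seq_len(nz)) arr[i, , ] <- slices[[i]]
  VoxelVolume(arr, voxelSize,
              provenance = sprintf("read %d slices from %s", nz, path))
}

# collapse RGB pages to one channel; keep integer grayscale as-is
asIntensity <- function(m) {
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m
}

#' Write a volume as a multi-page TIFF
#'
#' Values are stored as unsigned integers at the requested bit depth;
#' integer volumes within range round-trip losslessly through
#' [readVolume()].
#'
#' @param volume a [VoxelVolume-class].
#' @param path output file path.
#' @param bitsPerSample 8 or 16.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path, bitsPerSample = 8) {
  stopifnot(is(volume, "VoxelVolume"), bitsPerSample %in% c(8, 16))
  arr <- volumeData(volume)
  maxval <- 2^bitsPerSample - 1
  if (min(arr) < 0 || max(arr) > maxval)
    stop("volume intensities outside [0, ", maxval, "]; rescale first")
  slices <- lapply(seq_len(dim(arr)[1]),
                   function(i) round(arr[i, , ]) / maxval)
  tiff::writeTIFF(slices, path, bits.per.sample = bitsPerSample)
  invisible(path)
}

#' Effective detector pixel size
#'
#' The physical camera pixel size divided by the optical magnification
#' gives the effective pixel (and hence voxel) size in the sample plane:
#' a 6.5 µm camera pixel behind 3.6x optics resolves about 1.8 µm.
#'
#' @param cameraPixel physical camera pixel size, µm.
#' @param magnification optical magnification (dimensionless).
#' @return effective pixel size in µm.
#' @examples
#' effectivePixelSize(6.5, 3.6) # ~1.8 µm
#' @export
effectivePixelSize <- function(cameraPixel, magnification) {
  if (cameraPixel <= 0 || magnification <= 0)
    stop("cameraPixel and magnification must be positive")
  cameraPixel / magnification
}

#' Physical extent of a voxel grid
#'
#' @param shape integer voxel counts per axis.
#' @param voxelSize voxel edge length, µm.
#' @return per-axis physical extent in µm.
#' @examples
#' physicalExtent(c(230, 400, 400), 1.8) # 414 x 720 x 720 µm
#' @export
physicalExtent <- function(shape, voxelSize) {
  stopifnot(all(shape > 0), voxelSize > 0)
  shape * voxelSize
}

#' Extract a region of interest
#'
#' Coordinates are 0-based voxel indices in `(z, y, x)` order and the ROI
#' is half-open on each axis: it covers `origin` to `origin + shape - 1`
#' inclusive. The ROI must lie fully inside the volume.
#'
#' @param volume a [VoxelVolume-class].
#' @param origin integer(3), 0-based ROI corner.
#' @param shape integer(3), ROI size in voxels.
#' @return a [VoxelVolume-class] sharing the voxel size, with the crop
#'   recorded in its provenance.
#' @export
extractROI <- function(volume, origin, shape) {
  stopifnot(is(volume, "VoxelVolume"))
  origin <- as.integer(origin); shape <- as.integer(shape)
  d <- dim(volumeData(volume))
  if (any(origin < 0L) || any(shape <= 0L) || any(origin + shape > d))
    stop("ROI [", paste(origin, collapse = ","), "] + [",
         paste(shape, collapse = ","), "] exceeds volume bounds [",
         paste(d, collapse = ","), "]")
  arr <- volumeData(volume)[origin[1] + seq_len(shape[1]),
                            origin[2] + seq_len(shape[2]),
                            origin[3] + seq_len(shape[3]), drop = FALSE]
  VoxelVolume(arr, voxelSize(volume),
              provenance = c(provenance(volume),
                             sprintf("ROI origin (%s) shape (%s)",
                                     paste(origin, collapse = ","),
                                     paste(shape, collapse = ","))))
}

#' Read an analysis configuration file
#'
#' YAML or JSON, holding e.g. `voxel_size`, filter radii, window sizes, bin
#' edges and seeds. Returned as a named list; no schema is imposed beyond
#' requiring a positive `voxel_size` when present.
#'
#' @param path config file (`.yaml`, `.yml` or `.json`).
#' @return named list.
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$voxel_size) && cfg$voxel_size <= 0)
    stop("config voxel_size must be positive")
  cfg
}
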