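#' Topology-preserving 3D skeletonization
#'
#' Thins a fiber mask to a one-voxel-wide medial curve skeleton using
#' six-subiteration border thinning that deletes only simple points
#' (voxels whose removal provably preserves the number of connected
#' components and tunnels of object and background), with curve endpoints
#' preserved. Straight fibers thin to 26-connected center-line paths.
#'
#' @param mask a [PhaseMask-class] (fiber phase).
#' @param asMask return the skeleton as a logical array instead of a
#'   position matrix.
#' @return integer matrix of 0-based skeleton voxel positions with columns
#'   `z`, `y`, `x` (raster-scan order), or the logical skeleton array if
#'   `asMask = TRUE`. An empty mask yields an empty skeleton.
#' @examples
#' ph <- generateFibers(c(32, 32, 32), 1.8, fiberSpec(1, radius = 6), seed = 1)
#' seg <- segmentPhases(ph$volume)
#' nrow(skeletonize(seg$fiber))
#' @export
skeletonize <- function(mask, asMask = FALSE) {
  stopifnot(is(mask, "PhaseMask"))
  arr <- volumeData(mask)
  if (!any(arr)) {
    if (asMask) return(array(FALSE, dim(arr)))
    return(matrix(integer(), 0, 3, dimnames = list(NULL, c("z", "y", "x"))))
  }
  sk <- .thin3D(arr, dim(arr))
  if (asMask) return(sk)
  skeletonPositions(sk)
}

# 0-based (z,y,x) positions of TRUE voxels, raster order
skeletonPositions <- function(sk) {
  w <- which(sk) - 1L
  d <- dim(sk)
  pos <- cbind(z = w %% d[1],
               y = (w %/% d[1]) %% d[2],
               x = w %/% (d[1] * d[2]))
  storage.mode(pos) <- "integer"
  pos
}

#' Local fiber orientation from the second-order structure tensor
#'
#' At each query point the structure tensor — the Gaussian-weighted sum of
#' gradient outer products over a cubic window — is computed and the fiber
#' direction taken as the eigenvector of its smallest eigenvalue (the
#' direction of least intensity variation). Gradients are
#' Gaussian-derivative filtered at `gradientSigma`; the window side is the
#' physical window size converted to voxels and rounded to the nearest odd
#' count; the window weight is a Gaussian of SD one sixth of the window
#' side. Directions are folded to the upper hemisphere (antipodal
#' equivalence), then reported as azimuth theta in \[0,180) — the in-plane
#' angle of the `(x, y)` projection — and latitude phi in \[0,90\] — 90°
#' for in-plane fibers, 0° for fibers along the stack axis. A fiber along
#' the stack axis has no defined azimuth; theta is reported as 0 by
#' convention. Windows crossing the grid edge are clipped; points with
#' vanishing gradient energy are flagged invalid.
#'
#' @param x a [PhaseMask-class] (default tensor input: the binary mask) or
#'   a [VoxelVolume-class] (grayscale tensor input).
#' @param points integer matrix of 0-based `(z, y, x)` positions (e.g. from
#'   [skeletonize()]), or a single position vector.
#' @param windowUm window side in µm (default 57.6).
#' @param gradientSigma Gaussian-derivative scale in voxels (default 1).
#' @return data.frame with columns `z`, `y`, `x`, `rhoX`, `rhoY`, `rhoZ`,
#'   `theta`, `phi`, `valid`.
#' @export
localOrientation <- function(x, points, windowUm = 57.6, gradientSigma = 1) {
  stopifnot(is(x, "PhaseMask") || is(x, "VoxelVolume"))
  if (is.null(dim(points))) points <- matrix(points, 1)
  storage.mode(points) <- "integer"
  arr <- volumeData(x)
  if (is.logical(arr)) arr <- array(as.numeric(arr), dim(arr))
  d <- dim(arr)
  if (any(points < 0) || any(t(points) >= d))
    stop("query points must lie inside the grid")
  vs <- voxelSize(x)
  w <- roundToOdd(windowUm / vs)
  h <- (w - 1L) %/% 2L
  gz <- gaussGradientAxis(arr, gradientSigma, 0L)
  gy <- gaussGradientAxis(arr, gradientSigma, 1L)
  gx <- gaussGradientAxis(arr, gradientSigma, 2L)
  J <- .structureTensorAtPoints(gx, gy, gz, d, points, h, w / 6)
  n <- nrow(points)
  out <- data.frame(z = points[, 1], y = points[, 2], x = points[, 3],
                    rhoX = NA_real_, rhoY = NA_real_, rhoZ = NA_real_,
                    theta = NA_real_, phi = NA_real_, valid = FALSE)
  for (p in seq_len(n)) {
    tr <- J[p, 1] + J[p, 4] + J[p, 6]
    if (!is.finite(tr) || tr <= 1e-12) next   # constant window
    M <- matrix(c(J[p, 1], J[p, 2], J[p, 3],
                  J[p, 2], J[p, 4], J[p, 5],
                  J[p, 3], J[p, 5], J[p, 6]), 3, 3)
    ev <- eigen(M, symmetric = TRUE)
    v <- ev$vectors[, 3]                       # smallest eigenvalue
    if (v[3] < 0) v <- -v
    ang <- directionToAngles(v)
    out$rhoX[p] <- v[1]; out$rhoY[p] <- v[2]; out$rhoZ[p] <- v[3]
    out$theta[p] <- ang[["theta"]]; out$phi[p] <- ang[["phi"]]
    out$valid[p] <- TRUE
  }
  attr(out, "windowVoxels") <- w
  out
}

#' Fiber diameter at skeleton points by orthogonal ray casting
#'
#' Casts `nRays` evenly spaced diametric rays in the plane orthogonal to
#' the local fiber direction through each point and measures each ray's
#' in-mask chord; the reported diameter is the median chord times the
#' voxel size. The median is robust to the occasional ray that escapes
#' along a touching fiber. Points outside the mask are invalid (`NA`).
#'
#' @param mask the fiber [PhaseMask-class].
#' @param points integer matrix of 0-based `(z, y, x)` positions.
#' @param rho matrix of unit direction rows `(rhoX, rhoY, rhoZ)` matching
#'   `points`.
#' @param nRays number of diametric rays (default 64).
#' @return numeric vector of diameters in µm (`NA` where invalid).
#' @export
diameterAtPoint <- function(mask, points, rho, nRays = 64) {
  stopifnot(is(mask, "PhaseMask"))
  if (is.null(dim(points))) points <- matrix(points, 1)
  if (is.null(dim(rho))) rho <- matrix(rho, 1)
  storage.mode(points) <- "integer"
  nrm <- sqrt(rowSums(rho^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("rho rows must be unit vectors")
  chords <- .rayChords(volumeData(mask), dim(volumeData(mask)), points,
                       rho, as.integer(nRays), 0.5)
  chords * voxelSize(mask)
}

#' Full per-point fiber analysis of a segmented mask
#'
#' Convenience pipeline: skeletonize the fiber mask, estimate the local
#' orientation at every skeleton point, then the local diameter orthogonal
#' to that orientation.
#'
#' @param mask fiber [PhaseMask-class].
#' @param windowUm structure-tensor window, µm.
#' @param nRays diametric rays for the diameter estimate.
#' @param grayscale optional [VoxelVolume-class] to use as the tensor input
#'   instead of the binary mask.
#' @return data.frame of skeleton points: positions, `rhoX/Y/Z`, `theta`,
#'   `phi`, `diameter` (µm), `valid`.
#' @examples
#' ph <- generateFibers(c(48, 48, 48), 1.8, fiberSpec(2, radius = 6), seed = 1)
#' seg <- segmentPhases(ph$volume)
#' pts <- analyzeFibers(seg$fiber)
#' summary(pts$diameter)
#' @export
analyzeFibers <- function(mask, windowUm = 57.6, nRays = 64,
                          grayscale = NULL) {
  pos <- skeletonize(mask)
  if (nrow(pos) == 0)
    return(data.frame(z = integer(), y = integer(), x = integer(),
                      rhoX = numeric(), rhoY = numeric(), rhoZ = numeric(),
                      theta = numeric(), phi = numeric(),
                      diameter = numeric(), valid = logical()))
  src <- if (is.null(grayscale)) mask else grayscale
  ori <- localOrientation(src, pos, windowUm = windowUm)
  dia <- rep(NA_real_, nrow(pos))
  ok <- ori$valid
  if (any(ok))
    dia[ok] <- diameterAtPoint(mask, pos[ok, , drop = FALSE],
                               as.matrix(ori[ok, c("rhoX", "rhoY", "rhoZ")]),
                               nRays = nRays)
  ori$diameter <- dia
  ori$valid <- ori$valid & !is.na(dia)
  ori
}

#' Orientation histogram over skeleton points
#'
#' Bins the azimuth (span \[0,180)) or latitude (span \[0,90\]) of valid
#' points into equal-width bins; `binWidth` must divide the span. The last
#' latitude bin is closed so 90° is counted.
#'
#' @param points data.frame from [localOrientation()] / [analyzeFibers()].
#' @param axis `"azimuth"` or `"latitude"`.
#' @param binWidth bin width in degrees.
#' @return data.frame with `axis`, `lo`, `hi`, `count`, `fraction`.
#' @export
orientationHistogram <- function(points, axis = c("azimuth", "latitude"),
                                 binWidth = 10) {
  axis <- match.arg(axis)
  span <- if (axis == "azimuth") 180 else 90
  if (span %% binWidth != 0)
    stop("binWidth must divide the ", axis, " span of ", span, " degrees")
  vals <- if (axis == "azimuth") points$theta[points$valid]
          else points$phi[points$valid]
  binAngles(vals, 0, span, binWidth, axis)
}

#' Fiber diameter distribution
#'
#' Histograms valid skeleton-point diameters into half-open bins
#' `[lo, hi)`. The default edges 1, 5, 10, 25, 35, 45, 75 µm are the
#' reporting ranges used for micrometer-scale electrospun fibers.
#'
#' @param points data.frame with `diameter` and `valid` columns.
#' @param binEdges strictly increasing edges in µm.
#' @return data.frame with `lo`, `hi`, `count`, `percentage` (of binned
#'   points; sums to 100 when any point falls in range).
#' @export
diameterDistribution <- function(points,
                                 binEdges = c(1, 5, 10, 25, 35, 45, 75)) {
  if (any(diff(binEdges) <= 0)) stop("binEdges must be strictly increasing")
  binSizes(points$diameter[points$valid], binEdges, "µm")
}
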