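# Independent oracles and fixture builders used across the suite. These are
# deliberately naive re-derivations (loops, expand.grid enumerations) so
# that they share no code path with the package internals they check.

# exhaustive-scan maximum-entropy threshold: direct per-split entropy sums
kapurBrute <- function(counts, levels = seq_along(counts) - 1) {
  p <- counts / sum(counts)
  best <- -Inf
  bt <- NA
  for (t in seq_len(length(p) - 1)) {
    p0 <- p[1:t]
    p1 <- p[(t + 1):length(p)]
    if (sum(p0) == 0 || sum(p1) == 0) next
    q0 <- p0 / sum(p0)
    q1 <- p1 / sum(p1)
    H <- -sum(q0[q0 > 0] * log(q0[q0 > 0])) -
      sum(q1[q1 > 0] * log(q1[q1 > 0]))
    if (H > best + 1e-9) {
      best <- H
      bt <- levels[t]
    }
  }
  bt
}

# brute-force voxel-center rasterization of an infinite cylinder
cylinderVoxelOracle <- function(shape, anchorXYZ, dirXYZ, radiusVox) {
  g <- expand.grid(z = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                   x = 0:(shape[3] - 1))
  px <- g$x - anchorXYZ[1]
  py <- g$y - anchorXYZ[2]
  pz <- g$z - anchorXYZ[3]
  t <- px * dirXYZ[1] + py * dirXYZ[2] + pz * dirXYZ[3]
  d2 <- (px - t * dirXYZ[1])^2 + (py - t * dirXYZ[2])^2 +
    (pz - t * dirXYZ[3])^2
  sum(d2 <= radiusVox^2)
}

# brute-force voxel-center rasterization of a sphere
sphereVoxelOracle <- function(shape, centerXYZ, radiusVox) {
  g <- expand.grid(z = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                   x = 0:(shape[3] - 1))
  sum((g$x - centerXYZ[1])^2 + (g$y - centerXYZ[2])^2 +
        (g$z - centerXYZ[3])^2 <= radiusVox^2)
}

# angular difference on a circular span (degrees)
angDiff <- function(a, b, span = 180) {
  d <- abs(a - b) %% span
  pmin(d, span - d)
}

# distance of points (0-based z,y,x matrix) to a fiber axis, voxel units
distToAxis <- function(pos, fiberRow) {
  a <- c(fiberRow$anchorX, fiberRow$anchorY, fiberRow$anchorZ)
  d <- c(fiberRow$dirX, fiberRow$dirY, fiberRow$dirZ)
  px <- pos[, "x"] - a[1]
  py <- pos[, "y"] - a[2]
  pz <- pos[, "z"] - a[3]
  t <- px * d[1] + py * d[2] + pz * d[3]
  sqrt((px - t * d[1])^2 + (py - t * d[2])^2 + (pz - t * d[3])^2)
}

# per-skeleton-point orientation error vs the nearest true fiber axis
orientationErrors <- function(points, orientation, truth) {
  fb <- truth@fibers
  D <- sapply(seq_len(nrow(fb)), function(f) distToAxis(points, fb[f, ]))
  near <- apply(as.matrix(D), 1, which.min)
  ok <- orientation$valid
  list(theta = angDiff(orientation$theta[ok], fb$theta[near][ok]),
       phi = abs(orientation$phi[ok] - fb$phi[near][ok]))
}

# a PhaseMask built directly from a logical array
asFiberMask <- function(arr, voxelSize = 1) {
  new("PhaseMask", data = arr, phase = "fiber",
      voxelSize = as.numeric(voxelSize))
}

# a single straight cylinder mask along a given (x,y,z) unit direction
# through the grid center, built by enumeration (independent of the
# package rasterizer)
cylinderMask <- function(shape, dirXYZ, radiusVox, voxelSize = 1) {
  ctr <- (rev(shape) - 1) / 2  # (x, y, z)
  g <- expand.grid(z = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                   x = 0:(shape[3] - 1))
  px <- g$x - ctr[1]
  py <- g$y - ctr[2]
  pz <- g$z - ctr[3]
  t <- px * dirXYZ[1] + py * dirXYZ[2] + pz * dirXYZ[3]
  d2 <- (px - t * dirXYZ[1])^2 + (py - t * dirXYZ[2])^2 +
    (pz - t * dirXYZ[3])^2
  asFiberMask(array(d2 <= radiusVox^2, shape), voxelSize)
}
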