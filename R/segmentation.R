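#' 3D median filter over a discrete ball
#'
#' Noise suppression prior to thresholding. The physical radius (µm) is
#' converted to a voxel radius by rounding; a radius that rounds to zero
#' returns the input unchanged. Edges are handled by reflective padding.
#' With `perSlice = TRUE` the ball is restricted to the slice plane (a
#' disc), reproducing slice-wise 2D filtering of the stack.
#'
#' @param volume a [VoxelVolume-class].
#' @param radiusUm filter radius in µm (>= 0).
#' @param perSlice filter each z-slice independently in 2D.
#' @return the filtered [VoxelVolume-class].
#' @examples
#' v <- VoxelVolume(array(100, c(8, 8, 8)), 1.8)
#' identical(volumeData(medianFilterVolume(v, 1.8)), volumeData(v))
#' @export
medianFilterVolume <- function(volume, radiusUm, perSlice = FALSE) {
  stopifnot(is(volume, "VoxelVolume"))
  if (radiusUm < 0) stop("radius must be >= 0")
  r <- as.integer(round(radiusUm / voxelSize(volume)))
  arr <- volumeData(volume)
  if (r >= 1L)
    arr <- .medianFilterBall(arr, dim(arr), r, perSlice)
  new("VoxelVolume", data = arr, voxelSize = voxelSize(volume),
      provenance = c(provenance(volume),
                     sprintf("median filter r=%.3g µm (%d vox%s)", radiusUm,
                             r, if (perSlice) ", per-slice" else "")))
}

#' Maximum-entropy (Kapur) threshold of a gray-level histogram
#'
#' Chooses the threshold `t` maximizing the sum of Shannon entropies of the
#' two class-normalized histograms: levels `<= t` form the background
#' class, levels `> t` the foreground. Thresholds yielding an empty class
#' are excluded; among ties the lowest `t` is returned (deterministic).
#'
#' @param counts per-level histogram counts.
#' @param levels gray values corresponding to `counts` (default
#'   `0:(length(counts)-1)`).
#' @return the threshold gray level.
#' @examples
#' kapurThreshold(rep(1, 256)) # symmetric: 127
#' @export
kapurThreshold <- function(counts, levels = seq_along(counts) - 1) {
  stopifnot(length(counts) == length(levels))
  if (sum(counts > 0) < 2L)
    stop("histogram needs at least two non-empty gray levels")
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P0 <- cumsum(p)
  S0 <- cumsum(plogp)
  Ptot <- P0[length(p)]
  Stot <- S0[length(p)]
  # candidate split after index t (background = 1..t)
  t <- seq_len(length(p) - 1L)
  P1 <- Ptot - P0[t]
  valid <- P0[t] > 0 & P1 > 0
  H0 <- log(P0[t]) - S0[t] / P0[t]
  H1 <- log(P1) - (Stot - S0[t]) / P1
  score <- ifelse(valid, H0 + H1, -Inf)
  # ties (e.g. empty levels at the class boundary) resolve to the lowest
  # threshold; tolerance absorbs floating-point noise between algebraically
  # equal scores
  best <- max(score)
  levels[t[which(score >= best - 1e-9 * max(1, abs(best)))[1]]]
}

# Joint two-threshold maximum-entropy split: (t1, t2) maximizing the sum of
# the three class entropies (background <= t1 < fiber <= t2 < particle).
# The straightforward generalization of the single-threshold criterion;
# choosing both cuts jointly keeps the background/fiber valley from being
# swallowed by the dominant class, which a sequential two-pass scheme does
# on trimodal data. Ties resolve to the lowest thresholds.
kapurTwoThresholds <- function(counts, levels = seq_along(counts) - 1) {
  if (sum(counts > 0) < 3L)
    stop("histogram needs at least three non-empty gray levels")
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)
  S <- cumsum(plogp)
  n <- length(p)
  segH <- function(a, b) {  # entropy of class spanning levels a..b (indices)
    Pc <- P[b] - ifelse(a > 1, P[a - 1], 0)
    ifelse(Pc > 0, log(Pc) - (S[b] - ifelse(a > 1, S[a - 1], 0)) / Pc, -Inf)
  }
  best <- -Inf
  bt <- c(NA_real_, NA_real_)
  for (t1 in 1:(n - 2)) {
    if (P[t1] <= 0) next
    H0 <- segH(1, t1)
    t2 <- (t1 + 1):(n - 1)
    H <- H0 + segH(t1 + 1, t2) + segH(t2 + 1, n)
    H[!is.finite(H)] <- -Inf
    m <- max(H)
    thresh <- if (is.finite(best)) best + 1e-9 * max(1, abs(best)) else -Inf
    if (m > thresh) {
      best <- m
      i <- which(H >= m - 1e-9 * max(1, abs(m)))[1]
      bt <- c(levels[t1], levels[t2[i]])
    }
  }
  bt
}

# integer-level histogram of a volume; float data binned to 256 levels
volumeHistogram <- function(x, subset = NULL) {
  v <- if (is.null(subset)) as.vector(x) else x[subset]
  if (all(v == round(v)) && max(v) - min(v) <= 65535) {
    lev <- seq(min(v), max(v))
    counts <- tabulate(v - min(v) + 1L, nbins = length(lev))
  } else {
    br <- seq(min(v), max(v), length.out = 257)
    counts <- hist(v, breaks = br, plot = FALSE)$counts
    lev <- (br[-1] + br[-length(br)]) / 2
  }
  list(levels = lev, counts = counts)
}

#' Remove small connected components from a mask
#'
#' Despeckling for noisy segmentations: drops 26-connected components
#' smaller than `minVoxels`. Isolated noise voxels that survive the median
#' filter would otherwise seed spurious skeleton branches and phantom
#' particles. The default of 50 voxels is below the voxel count of the
#' smallest resolvable fiber (radius one voxel) crossing a typical
#' analysis volume, so real structures are retained.
#'
#' @param mask a [PhaseMask-class].
#' @param minVoxels smallest component kept.
#' @return the cleaned [PhaseMask-class].
#' @export
removeSmallComponents <- function(mask, minVoxels = 50) {
  stopifnot(is(mask, "PhaseMask"))
  lb <- labelComponents(volumeData(mask), 26)
  if (lb$n == 0) return(mask)
  keep <- which(tabulate(lb$labels[lb$labels > 0L], lb$n) >= minVoxels)
  arr <- array(lb$labels %in% keep, dim(volumeData(mask)))
  new("PhaseMask", data = arr, phase = mask@phase,
      voxelSize = voxelSize(mask),
      provenance = c(provenance(mask),
                     sprintf("removed components < %d voxels", minVoxels)))
}

#' Two-stage maximum-entropy phase segmentation
#'
#' Separates the volume into background, polymer fiber and ceramic
#' particle phases with maximum-entropy thresholding. The two cuts
#' `t1 < t2` are chosen jointly as the pair maximizing the summed Shannon
#' entropies of the three class-normalized histograms (the multilevel form
#' of the Kapur criterion): background is `<= t1`, fiber `(t1, t2]`,
#' particle `> t2`, with inclusive-low semantics throughout. Joint
#' optimization matters on real trimodal µCT histograms: cutting
#' background/material first with a single-threshold pass tends to land on
#' the particle valley instead, because the strongly absorbing ceramic
#' class dominates the entropy balance.
#'
#' If fewer than three populated levels exist the function falls back to a
#' single-threshold material-only segmentation with a warning. A
#' three-phase split presumes a ceramic phase is present: on a two-class
#' fiber-only volume with blur or noise it would split the fiber class
#' itself. For samples known to contain no particles, request
#' `stages = 1`, which thresholds once and labels all material as fiber.
#'
#' @param volume a [VoxelVolume-class] (typically median-filtered first).
#' @param stages 2 (background/fiber/particle, default) or 1
#'   (background/material only).
#' @return list with [PhaseMask-class] elements `material`, `fiber`,
#'   `particle`, and `thresholds = c(t1, t2)` (`t2` is `NA` after
#'   fallback or with `stages = 1`).
#' @examples
#' ph <- generateFibers(c(32, 32, 32), 1.8, fiberSpec(3, radius = 5), seed = 1)
#' seg <- segmentPhases(ph$volume)
#' seg$thresholds
#' @export
segmentPhases <- function(volume, stages = 2) {
  stopifnot(is(volume, "VoxelVolume"), stages %in% c(1, 2))
  arr <- volumeData(volume)
  vs <- voxelSize(volume)
  h1 <- volumeHistogram(arr)
  nLevels <- sum(h1$counts > 0)
  if (nLevels < 2L)
    stop("volume is constant: no intensity classes to separate")
  t2 <- NA_real_
  if (stages == 2 && nLevels >= 3L) {
    tt <- kapurTwoThresholds(h1$counts, h1$levels)
    t1 <- tt[1]
    t2 <- tt[2]
    material <- arr > t1
    particle <- material & arr > t2
    fiber <- material & !particle
  } else {
    if (stages == 2)
      warning("degenerate histogram: fiber/particle split skipped; ",
              "returning material-only segmentation")
    t1 <- kapurThreshold(h1$counts, h1$levels)
    material <- arr > t1
    fiber <- material
    particle <- array(FALSE, dim(arr))
  }
  prov <- c(provenance(volume),
            sprintf("kapur thresholds t1=%.6g t2=%.6g", t1, t2))
  mk <- function(data, phase) new("PhaseMask", data = data, phase = phase,
                                  voxelSize = vs, provenance = prov)
  list(material = mk(material, "material"), fiber = mk(fiber, "fiber"),
       particle = mk(particle, "particle"), thresholds = c(t1 = t1, t2 = t2))
}
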