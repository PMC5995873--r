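---
title: "Quantifying fibrous scaffold structure from micro-CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrous scaffold structure from micro-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffoldCT)
```

## The measurement problem

Electrospun scaffolds are nonwoven meshes of polymer microfibers, often
loaded with ceramic microparticles that appear as a third, strongly
absorbing intensity class in µCT. Their biological performance is usually
discussed in terms of a handful of structural quantities: porosity, the
fiber diameter distribution, the degree and direction of fiber alignment,
and the size census of particle aggregates. scaffoldCT computes all of
these from a reconstructed grayscale volume, and ships a phantom generator
with exact ground truth so that each estimator's error can be measured
instead of assumed.

All volumes are `(z, y, x)` arrays with the slice-stacking axis first and
a single isotropic voxel size in µm. Calibration is explicit: the voxel
size is user-supplied (typically the camera pixel size divided by the
optical magnification, see `effectivePixelSize()`), never read from image
metadata, because TIFF resolution tags are written too inconsistently
across reconstruction pipelines to be load-bearing.

## Segmentation model

Noise is suppressed with a 3D median filter over a discrete ball whose
radius is given in µm and rounded to voxels (`medianFilterVolume()`; a
`perSlice` flag restricts the ball to a disc for slice-wise 2D filtering).
Reflective padding handles edges; a radius that rounds to zero voxels is
the identity.

Phases are separated by maximum-entropy thresholding. For a histogram
`p` over gray levels, the single-threshold Kapur criterion picks the `t`
maximizing the sum of the Shannon entropies of the two class-normalized
histograms (`kapurThreshold()`; levels `<= t` are the lower class, ties
resolve to the lowest `t`). For three classes, `segmentPhases()` selects
the *pair* `t1 < t2` that jointly maximizes the three-class entropy sum.

The joint choice is a deliberate design decision. The obvious sequential
alternative — first split background from material with one threshold,
then split the material histogram into fiber and particle — fails on
realistic trimodal volumes: with a dominant background class and a small
but far-displaced ceramic class, the single-threshold criterion prefers
the particle valley, classifying the entire fiber class as background. On
three-level noiseless phantoms the joint criterion recovers every phase
voxel-exactly (all valid threshold pairs tie at zero within-class entropy
and the tie-break takes the lowest, which sits exactly at the class
edges), and with additive noise at 15% of the class separation the
per-voxel error stays below 2%.

Two practical helpers round out the module. `segmentPhases(stages = 1)`
performs a material-only split, for samples known to contain no ceramic
phase — forcing a three-class split there would cut the fiber class in
two. `removeSmallComponents()` drops 26-connected components below a
voxel-count floor (default 50): isolated noise voxels that survive a
one-voxel median ball otherwise seed spurious skeleton branches and
phantom particles. Fifty voxels is well below the footprint of the
smallest resolvable fiber crossing an analysis volume, so real structure
is untouched.

## Fiber analysis

`skeletonize()` thins the fiber mask to a one-voxel-wide curve skeleton
with six-subiteration border thinning. Only *simple points* are deleted —
voxels whose 3×3×3 neighborhood has exactly one 26-connected object
component and exactly one 6-connected background component touching a
face neighbor — so the number of connected components and tunnels is
provably preserved; voxels with a single object neighbor (curve
endpoints) are kept. The skeleton is accepted by contract (unit width,
topology, centredness within a voxel on test cylinders), not by matching
any particular published implementation voxel-for-voxel.

At each skeleton point, `localOrientation()` computes the second-order
structure tensor: Gaussian-derivative gradients (σ = 1 voxel) accumulated
over a cubic window with a Gaussian weight of SD one sixth of the window
side. The default window of 57.6 µm converts to 33 voxels at 1.8 µm
(rounded to odd for a centered window). The fiber direction is the
eigenvector of the smallest eigenvalue, i.e. the direction of least
intensity variation. Directions are antipodally equivalent, so ρ is
folded to the non-negative-z hemisphere; azimuth θ is the in-plane angle
of the `(x, y)` projection in [0°,180°), latitude φ is 90° for in-plane
fibers and 0° for fibers along the stack axis. That latitude convention
follows from how layered deposition orients fibers: a scaffold built
slice by slice concentrates latitude near 90°. For a fiber exactly along
the stack axis the azimuth is undefined and reported as 0 by convention;
windows clipped at the grid edge are summed over their intersection with
the grid; a constant window (zero gradient energy) marks the point
invalid. By default the tensor is computed on the binary mask (smoothed
implicitly by the Gaussian-derivative kernels); passing the grayscale
volume instead is supported via the `grayscale` argument of
`analyzeFibers()`.

`diameterAtPoint()` casts 64 evenly spaced diametric rays in the plane
orthogonal to ρ and reports the median in-mask chord times the voxel
size. The median resists the occasional ray that escapes along a
touching fiber; the chord adds half a sampling step (0.25 voxel) per side
to center the truncation error of the 0.5-voxel ray sampling. Rays that
leave the *grid* while still inside the mask measure a field-of-view
clip, not a fiber surface, so they are censored; a point with more than
half its rays censored is invalid. Without this censoring, fibers exiting
the volume acquire spuriously small diameters at boundary skeleton
points.

Distributions are plain tables: `orientationHistogram()` bins azimuth
over [0°,180°) or latitude over [0°,90°] (top bin closed), and
`diameterDistribution()` uses half-open µm bins with default edges 1, 5,
10, 25, 35, 45, 75 — the ranges in which micrometer-scale electrospun
fiber diameters are conventionally reported.

## Particle analysis

`labelComponents()` labels the particle mask at 6-, 18- or
26-connectivity. The default of 18 encodes the rule that aggregates are
merged when they touch at faces or edges but not at corners only. Labels
are assigned in raster-scan order of first appearance, making the
labeling deterministic. `particleTable()` converts components to physical
volumes (`voxelCount × voxelSize³`) and equivalent spherical diameters
`(6V/π)^{1/3}`; one voxel at 1.8 µm is 5.832 µm³, which is the natural
detection floor (equivalent diameter 2.23 µm). Aggregates touching the
volume border are kept but flagged, since their volumes are truncated;
downstream counts can include or exclude them explicitly.
`particleSizeDistribution()` defaults to the reporting bins 5.83, 1000
and 10⁶ µm³ (equivalent diameters 2.23, 12.4 and 124 µm).

## Porosity and group statistics

`porosity()` reports both the material fraction (material voxels over
total voxels) and its complement; the two sum to 100 exactly. Porosity —
the complement — is the quantity conventionally quoted for scaffolds
(values around 70–80% for electrospun meshes); emitting both removes any
ambiguity about which ratio is meant.

`groupCompare()` runs one-way ANOVA (`stats::aov`) and Tukey HSD
(`stats::TukeyHSD`, studentized-range distribution, Tukey–Kramer for
unbalanced groups) over named groups of measurements. Pairwise
significance is decided at `alpha` (default 0.05). The reporting tiers
`*` p < 0.05, `**` p < 0.1, `***` p < 0.3, `N.S.` p > 0.8 are attached as
labels only; they are unconventional (the usual convention puts more
asterisks at smaller p) and no decision in the package depends on them.

## The phantom generator

The generator is the package's validation instrument, and its defaults
are fixed to the imaging scenario the analysis targets:

- **Geometry.** Straight cylindrical fibers spanning the volume, rasterized
  by the rule that a voxel belongs to a shape iff its center is inside
  (the same rule the brute-force counting oracles use, so truth and
  rasterization agree up to a surface-voxel bound). Fibers may overlap, as
  in real nonwovens; overlapping voxels count once. Real electrospun
  fibers curve over millimetres; over the few-hundred-µm windows analyzed
  here, straight segments are an adequate local model, and the curvature
  statistics are not known well enough to emulate.
- **Orientation.** Azimuth uniform on [0°,180°) in `random` mode, wrapped
  normal around a preferred azimuth in `aligned` mode (a single
  concentration parameter). Latitude uniform in [50°, 90°] by default,
  reflecting the near-in-plane fiber beds that layer-by-layer deposition
  produces.
- **Particles.** Spheres with volumes from a configurable distribution;
  with probability `clustering` a particle is seeded touching an existing
  one (centers at 0.8 of the radius sum, guaranteeing voxel overlap) and
  joins its aggregate. Particles overwrite fiber voxels, embedding the
  ceramic in the fiber matrix. Particles below one voxel are recorded in
  the truth but flagged sub-resolution.
- **Intensities.** Background/fiber/particle at 30/100/220 on an 8-bit
  scale: three separable classes with the weakly absorbing polymer between
  the background and the strongly absorbing ceramic.
- **Degradation.** Normalized separable Gaussian blur (detector point
  spread) then additive zero-mean Gaussian noise, clipped to the gray
  range. Noise SD 14 against the 70-level background/fiber separation
  corresponds to SNR 5, the regime the recovery experiments run at.

What the phantom does *not* emulate: phase-contrast fringes at material
boundaries, reconstruction ring artifacts, beam hardening, fiber
curvature, and beads-on-string morphologies. Passing recovery tests on
phantoms therefore demonstrates the estimators' correctness under the
stated imaging model, not robustness to every artifact a beamline can
produce.

`truthSummary()` converts the generative truth into the same tables the
analysis emits (orientation histograms, diameter and particle size
distributions, porosity) — computed analytically from the truth, never
from the rasterized volume — together with a discretization bound (the
surface-voxel budget) within which analytic and voxel-counted volumes
must agree.

## Numerical choices and degenerate inputs

- Thresholds use inclusive-low semantics (`level <= t` is the lower
  class) everywhere; ties resolve to the lowest threshold, with a 1e-9
  relative tolerance absorbing floating-point differences between
  algebraically equal entropy scores.
- Histograms are native gray levels for integer volumes and 256 equal
  bins for floating-point volumes.
- Volumes with fewer than three populated gray levels fall back to
  material-only segmentation with a warning; constant volumes are an
  error.
- Empty masks skeletonize to empty point sets; empty particle grids give
  empty tables; `n = 0` generator specs are identities.
- Reproducibility: every stochastic operation takes an explicit seed and
  pins the RNG kind, so identical (spec, seed) pairs reproduce volumes
  bit-for-bit without disturbing the caller's RNG state.

## Validation experiments and problem sizes

The test suite validates each stage against independent oracles:
brute-force voxel enumeration for rasterization, an exhaustive entropy
scan for thresholding, hand-computed ANOVA mean squares, and analytic
geometry for porosity and histogram weights. The headline recovery
experiments, also recomputed by `scripts/acceptance.R`, use: ten 128³
aligned phantoms (20 fibers, 3° jitter, SNR 5) for orientation — mean
absolute azimuth and latitude errors around 1.6° and 2.9°, against a 5°
acceptance bound; 96³ phantoms with three fibers per radius for diameter
recovery across 3–10-voxel radii (kept sparse so fibers rarely merge;
merged composites have no single-fiber diameter) — median error within
one voxel; and a 128³ end-to-end pipeline with both phases, blur and
noise, which completes in well under a minute and recovers porosity
within a few percentage points of truth. These sizes give stable
statistics while keeping a full validation run to a couple of minutes.

## Known limitations

- Thinning over-erodes shapes that are *perfectly* tie-symmetric about an
  inter-voxel plane (a 2×2×L bar, or a cylinder whose axis lies exactly
  between voxel rows): the final two-voxel-wide sheet unzips. The
  reference 3D thinning in scikit-image (Lee's algorithm) deletes such
  shapes entirely under the same conditions. Generic, noisy, or
  odd-centered structures — i.e. real data — are unaffected.
- Blur plus entropy thresholding includes part of the blurred fiber halo
  in the material class, biasing porosity down and diameters up by
  roughly the blur width; the bias is visible in the worked example and
  is inherent to global thresholding of band-limited images.
- Segmentation is purely intensity-based; phase-retrieval preprocessing,
  learned segmentation, and watershed splitting of touching aggregates
  are out of scope.
- Anisotropic voxels are rejected rather than resampled, and volumes must
  fit in memory.
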