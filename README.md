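# scaffoldCT

Quantitative 3D analysis of micro-computed-tomography (µCT) volumes of
electrospun fibrous scaffolds — porous polymer meshes, optionally loaded
with ceramic (e.g. calcium-phosphate) microparticles, of the kind used as
bone tissue-engineering substrates. Given a reconstructed grayscale volume
with an isotropic voxel size, the package answers the structural questions
such scaffolds are characterized by:

- **Phase segmentation.** Background, polymer fiber and ceramic particle
  classes are separated by maximum-entropy (Kapur) thresholding after 3D
  median filtering. The two cuts `t1 < t2` are chosen jointly to maximize
  the summed Shannon entropies of the three class-normalized histograms —
  the multilevel form of the criterion
  `argmax_t H(p | levels ≤ t) + H(p | levels > t)`.
- **Fiber orientation.** A one-voxel-wide, topology-preserving skeleton is
  extracted from the fiber mask by 3D thinning. At each skeleton point the
  second-order structure tensor `J = Σ_w g · ∇I ∇Iᵀ` is computed over a
  local window (57.6 µm by default); the fiber direction ρ is the
  eigenvector of the smallest eigenvalue, reported as azimuth θ ∈ [0°,180°)
  in the slice plane and latitude φ ∈ [0°,90°] (90° = in-plane).
- **Fiber diameter.** At each skeleton point, diametric rays are cast in
  the plane orthogonal to ρ; the median in-mask chord times the voxel size
  is the local diameter.
- **Particle aggregates.** Connected components of the particle mask at
  18-connectivity (faces and edges merge, corner contact does not), sized
  as equivalent spheres, `d = (6V/π)^(1/3)`.
- **Porosity.** `100·(1 − material voxels / total voxels)`.
- **Group statistics.** One-way ANOVA with Tukey HSD post-hoc pairwise
  comparison across sample groups.

A synthetic phantom generator (`generateFibers`, `addParticles`,
`degradeVolume`) produces µCT-like volumes of straight cylindrical fibers
and clustered spherical particles with **exact ground truth** (per-fiber
axes/radii/angles, per-aggregate voxel counts, exact phase voxel counts),
so every stage of the chain is validated by recovery experiments rather
than by eye.

## Worked example

A full pipeline on a 128³ phantom (1.8 µm voxels): aligned fibers at 90°
azimuth with particle aggregates, degraded by blur and noise, then
analyzed.

```r
library(scaffoldCT)
vs <- 1.8
spec <- fiberSpec(12, radius = list(kind = "uniform", min = 7, max = 14),
                  orientationMode = "aligned", alignedAzimuth = 90,
                  angularJitter = 4)
ph <- generateFibers(c(128, 128, 128), vs, spec, seed = 42)
ph <- addParticles(ph$volume, ph$truth,
                   particleSpec(10, volume = list(kind = "uniform",
                                                  min = 50, max = 800),
                                clustering = 0.3), seed = 43)
noisy <- degradeVolume(ph$volume, blurSigma = 1.8, noiseSd = 10, seed = 44)

seg <- segmentPhases(medianFilterVolume(noisy, 1.8))
seg$thresholds
#>        t1        t2
#>  42.20891 115.64985

por <- porosity(seg$material)
#> porosity 87.52% (truth 90.74%)

fiber <- removeSmallComponents(seg$fiber)
pts <- analyzeFibers(fiber)          # skeleton + orientation + diameter
orientationHistogram(pts, "azimuth", 20)
#>      axis  lo  hi count    fraction
#> 4 azimuth  60  80   387 0.044621238
#> 5 azimuth  80 100  7992 0.921480457   <- 92% of points near 90 degrees
#> ...
median(pts$diameter[pts$valid])
#> [1] 27

tab <- particleTable(labelComponents(
         removeSmallComponents(seg$particle, 4), 18), vs)
particleSizeDistribution(tab)
#>        lo    hi unit count percentage
#> 1    5.83 1e+03  µm³     4         80
#> 2 1000.00 1e+06  µm³     1         20
```

The aligned phantom's azimuth histogram concentrates 92% of skeleton
points in the 80–100° bin, as expected for a 90° preferred direction with
4° jitter. The measured porosity (87.5%) sits ~3 points below the
generative truth (90.7%) because blur spreads the fiber boundary and the
entropy threshold includes part of that halo; the same halo inflates the
median diameter slightly. The particle census splits aggregates into the
5.83–1000 µm³ range (equivalent diameter 2.23–12.4 µm) and the larger
1000–10⁶ µm³ range.

## A note on units and conventions

Volumes are numeric 3D arrays in `(z, y, x)` order with the slice-stacking
axis first; voxel coordinates are 0-based; physical calibration is always
an explicit voxel size in µm (TIFF resolution tags are not trusted).
Latitude is defined so that fibers lying in the slice plane have φ = 90°
and fibers along the stack axis have φ = 0°.
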