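# CentroSMLM

Single-molecule localization microscopy (SMLM) analysis of centromeric
protein clusters.

In early G1, CENP-A — the centromeric histone H3 variant — forms
rosette-like clusters of ~250–300 nm outer diameter with a ~100 nm central
cavity occupied by its chaperone HJURP; later in G1 the clusters compact
into filled globules. Quantifying this organization from dSTORM/PALM
localization tables requires a chain of corrections and statistics that this
package implements end to end:

* **Localization tables** — canonical CSV I/O (plus a ThunderSTORM-style
  reader shim), histogram rendering with strict count conservation,
  float-TIFF images and MRC volumes.
* **Corrections** — drift correction by iterative cross-correlation of
  temporal subset histograms (subpixel, lateral from XY and axial from the
  XZ/YZ projections); two-colour chromatic correction with a full
  second-order bivariate polynomial fitted to bead pairs; merging of
  consecutive localizations of one fluorophore (chains anchored at the
  origin event within 50 nm, coordinates averaged, photons summed); FRC
  (Fourier ring correlation) resolution at 10 nm pixels and 90 frequency
  points with the 1/7 threshold.
* **Voronoi density analysis** — per-localization densities (inverse cell
  measure, first-rank neighbour averaged), density map rendering, and
  density-threshold segmentation with a Monte-Carlo (uniform-field) rule.
* **Cluster averaging** — particle picking, normalization by pixel standard
  deviation, iterative alignment to the rotationally averaged sum, radial
  profiles with per-cell mean/sd, and the half-radius statistic (the radius
  where the cumulative radial profile reaches 50%; exactly half the radius
  for a uniform sharp-edged disk).
* **Center-of-mass profiles** — cluster centres M = (1/N) Σ x_i from all
  localizations within 250 nm, radial histograms on [0, 200) nm with
  d = 20 nm bins, corrected by the ring areas S_j = π(2j − 1)d², normalized
  to unit sum, averaged per cell — the quantitative comparison of CENP-A
  shell versus HJURP core.
* **3D reconstruction** — common-line angular reconstitution (sinogram
  correlation with a robust triplet bootstrap and coordinate-descent
  refinement) followed by weighted, filtered back-projection and
  re-projection validation.
* **Synthetic data** — a fully seeded generator of shell/filled/disk cluster
  fields with blinking, localization noise, drift, chromatic shift and
  background, plus phantom volumes and projections, so that every stage is
  testable against ground truth without microscope data.

## Worked example

Simulate four rosette clusters with drift, run the correction chain,
segment, and profile:

```r
library(CentroSMLM)

models <- lapply(1:4, function(i)
  ClusterModel("shell", outerDiameter = 280, innerDiameter = 100,
               nMolecules = 500L,
               center = c(600 + 800 * ((i - 1) %% 2),
                          600 + 800 * ((i - 1) %/% 2), 300)))
acq <- AcquisitionModel(nFrames = 8000L, meanOnFrames = 3, locPrecision = 10,
                        backgroundDensity = 1e-3,
                        fieldSize = c(2000, 2000, 600),
                        drift = linearDrift(8000L, c(60, 40)), seed = 42L)
sim <- simulateField(models, acq, dims = 2)
sim$table
#> LocalizationTable: 6032 localizations (2D), 1 channel(s), frames 8..8000

traj <- estimateDrift(sim$table, nSubsets = 10, pixelSize = 20)
tab  <- mergeConsecutive(correctDrift(sim$table, traj))
length(sim$table); length(tab)
#> 6032 -> 2036 records (three consecutive emissions per molecule on average)

vd  <- voronoiDensities(tab, dims = 2)
seg <- segmentClusters(vd, tab, alpha = 0.05, nSim = 5, minSize = 50, seed = 1)
clusterTable(seg)[, c("label", "n", "cx", "cy", "eqDiameter")]
#>    label   n     cx     cy eqDiameter
#>        1 504  595.0 1400.1      273.8
#>        2 500  594.8  603.5      267.3
#>        3 496 1402.7  596.2      270.8
#>        4 492 1398.1 1400.3      265.3

prof <- comRadialProfile(tab, as.matrix(clusterTable(seg)[, c("cx", "cy")]))
round(profileNormalized(prof), 3)
#> 0.004 0.018 0.119 0.227 0.201 0.225 0.166 0.037 0.002 0.000
halfRadius(prof)
#> 93 nm
frcResolution(tab, seed = 1)$resolution
#> 117.6 nm
```

The segmentation recovers the four clusters at their true positions with
equivalent diameters inside the configured 250–300 nm range; the area-
corrected radial profile is empty at the centre and peaks on the 50–140 nm
annulus, exactly the hollow-rosette signature, and sums to one.

The same stages run as one reproducible pipeline (`runPipeline()`,
YAML-configurable, deterministic under its seed), also available from the
shell via `inst/scripts/run-pipeline.R`.

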