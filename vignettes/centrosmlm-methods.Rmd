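---
title: "CentroSMLM: models, corrections and reconstruction methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CentroSMLM methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

CentroSMLM quantifies the nanoscale organization of centromeric protein
clusters from single-molecule localization microscopy (SMLM) data: CENP-A
forms rosette-like clusters of ~250–300 nm outer diameter with a ~100 nm
central cavity in early G1, with the chaperone HJURP at the centre, and
compacts into filled globules later in G1. This vignette explains the
models behind every stage, the tunable parameters, and the numerical and
design choices made where the methods left room.

## The localization table and its conventions

Every stage consumes and produces a `LocalizationTable`: one row per fitted
single-fluorophore event with a 1-based frame, coordinates in nanometres
(z optional), photon count and channel. Coordinates are continuous, with
the origin at the field corner and a right-handed axis order. Histogram
rendering uses half-open pixel intervals `[k p, (k+1) p)` with floor
binning; the pixel sum always equals the number of in-bounds localizations.
This one convention is shared by every consumer (drift subsets, FRC
half-images, density maps, cluster boxes), so rendered quantities are
directly comparable.

## Synthetic data generator

Because SMLM centromere datasets are not publicly deposited, the package
ships a seeded generator whose defaults encode the imaging conditions the
analyses target:

* **Cluster geometry.** `ClusterModel` supports a hollow `shell` (outer
  diameter 280 nm, cavity 100 nm by default — the middle of the observed
  250–300 nm range and the reported ~100 nm cavity), a `filled` Gaussian
  ball with FWHM equal to half the outer diameter (the compact late-G1
  state), and a flat `disk` (the mitotic plate). The shell support follows
  the imaging dimensionality: 3D simulations draw a uniform spherical shell
  between the radii; 2D simulations draw the corresponding annular ring.
  The annular reading matters: 2D images of the rosettes show hollow rings,
  whereas the projection of a *uniform* 3D shell of this geometry has an
  analytic centre-to-peak ratio of only 0.73–0.75 at 10–20 nm pixels — a
  projected uniform shell can never show the pronounced interior dip the
  2D data exhibit, while the annular support reproduces it robustly.
  Angular sub-structure is available as raised-cosine azimuthal lobes
  (`subclusterCount`), matching the qualitative lobedness of real rosettes.
* **Blinking.** Each molecule emits in a single run of consecutive frames
  with geometric run length (mean `meanOnFrames`, default 3) — the
  memoryless model that matches the consecutive-event merging assumption.
  Every emitting frame yields one localization: true position + per-frame
  drift + Gaussian localization error (`locPrecision`, default 10 nm
  lateral / 25 nm axial) + polynomial chromatic shift (channel 2 only).
* **Background** is uniform over the field at `backgroundDensity`
  localizations per µm² per frame (default 1e-3).
* **Determinism.** All randomness flows from one explicit seed
  (`withr::with_seed`); identical seeds give bit-identical tables. Nothing
  uses the global RNG state.

The generator emulates localization lists, not raw camera frames: there is
no PSF, camera noise, or dye photophysics beyond geometric on-times.
Passing tests therefore demonstrate the correctness of the *analysis*
chain, not robustness to fitting artifacts (mislocalizations, overlapping
emitters, z-dependent PSF distortions) that real data add before the
pipeline begins.

## Drift correction

The acquisition is divided into `nSubsets` (default 10) consecutive frame
subsets; each is rendered at 20 nm pixels and registered to the first
subset by FFT cross-correlation. Sparse single-molecule histograms make the
(broad) correlation peak noisy, so subset images are smoothed with a
Gaussian of 2 px before correlation, and the peak is refined to 1/20 px by
a local matrix-multiply DFT upsampling. Lateral drift comes from the XY
projection; axial drift (3D) is the mean of the shifts found in the XZ and
YZ projections. Anchor shifts at subset mid-frames are interpolated
linearly; the procedure repeats on the corrected table (default 3 passes,
early stop below 1 nm) and reports the per-pass RMS so the refinement is
inspectable. With 10 subsets of ≥ 10⁴ localizations the anchor error is
~2–3 nm; a 100 nm linear drift over 10⁴ frames is recovered to < 5 nm RMS.

## Chromatic correction

Bead pairs calibrate a full second-order bivariate polynomial
`(1, x, y, x², xy, y²)` per axis — six coefficients, hence at least six
beads in general position; collinear designs are rejected as rank
deficient. The fitted shift is subtracted from the non-reference channel
only; reference-channel records are returned bit-identical.

## Merging of consecutive localizations

For each origin localization N on frame n, candidates on frame n+1 within
50 nm **of N** are searched; the nearest is absorbed (ties to the lower
id), and the search continues frame by frame until no candidate remains.
Distances are always measured to the origin event, not the last chain
member — the literal reading of the procedure. Chains are seeded in
(frame, id) order, each localization joins at most one chain, and only
same-channel events chain (distinct fluorophores cannot be one molecule).
The merged record keeps the origin's frame and id, averages coordinates
unweighted, and sums photons — total photons are conserved exactly. The
test suite checks the implementation record-for-record against an
independent brute-force tracer written directly from the rule.

## FRC resolution

Localizations are split per-event by a seeded Bernoulli(0.5); both halves
are rendered at 10 nm pixels on a common square grid; the normalized
cross-correlation over rings of spatial frequency is evaluated at 90
points, and the resolution is 1/q at the first 1/7 crossing, linearly
interpolated. Merging is applied before FRC (the corrected data are what
is resolution-rated); otherwise repeated localizations of one molecule
appear in both halves and inflate the correlation. Identical half-sets
give FRC ≡ 1 exactly; curves that never cross report an "unresolved"
sentinel with the last FRC value.

## Voronoi densities and segmentation

2D tessellations are exact (deldir); cells touching the (5% expanded)
bounding window are flagged unbounded and excluded from density
statistics. No 3D tessellation library being available, the 3D diagram is
discrete: voxels (edge chosen so the grid stays below 4e6 voxels) are
assigned to their nearest localization; cell volumes are voxel counts ×
voxel volume, coincident-voxel points share their group's cell, and
adjacency is face-sharing of discrete cells — a voxel-resolution
approximation of Delaunay adjacency.

The density estimator is the first-rank average (mean of inverse cell
measure over a cell and its Delaunay neighbours); the raw inverse measure
is also exposed. Segmentation thresholds this density either absolutely or
by the Monte-Carlo rule: the density exceeded by at most α (default 0.05)
of the localizations of `nSim` (default 10) uniform fields matched in count
and extent. Above-threshold localizations are linked through Delaunay
edges whose **both** endpoints are above threshold and whose length is at
most `maxEdge` (default 5× the median nearest-neighbour distance); without
the length cut, single Delaunay edges spanning the empty space between
clusters merge them. Components below `minSize` (default 25) drop to
background. Equivalent diameters use the robust occupied measure (member
count × median member cell measure), which border cells reaching into
empty space would otherwise inflate.

Two caveats are worth stating. The exact segmentation algorithm of the
original density-based software is not public; this thresholding rule is a
documented stand-in for it. And cluster count is *not* globally monotone
in the threshold for any density-threshold method (clusters can split
before dissolving; background fragments can pass `minSize` at low
thresholds); at and above the Monte-Carlo threshold, where segmentation is
actually operated, counts decrease as the threshold rises.

## Cluster averaging and radial statistics

Cluster windows are picked from a rendering either at supplied centres or
automatically as local maxima of a Gaussian-smoothed image above an
intensity percentile. The detection sigma defaults to 100 nm — the scale
of a diffraction-limited spot — because peaks of the *low-resolution*
image sit at the centre of ring-like clusters, whereas finer smoothing
would detect the ring crest instead.

Images are normalized by dividing by their pixel standard deviation; the
mean is deliberately not subtracted (the literal reading of the
normalization step; the alternative is a documented open point).
Alignment iterates: (1) the stack sum is rotationally averaged to form the
reference; (2) each image is aligned by exhaustive rotation search
(default step 2°) plus subpixel translation; (3) images are re-transformed
from their pristine originals (one resampling pass, no compounding blur).
Because the reference is rotationally symmetric by construction, the
rotation scores are nearly flat: per-image rotations are reported but are
essentially unconstrained, and the alignment is driven by the
translations. Iteration stops when the mean update falls below 0.1 px and
0.5°.

Radial profiles bin pixels by centre distance in `[jd − d, jd)` rings; the
same half-open convention serves the localization histograms. Per-cell
statistics follow the stated procedure: the aligned particles of each cell
are averaged (the cell *mean* image, so cells with different particle
counts weigh equally), each cell average is radially profiled, and the
pointwise mean and *sample* standard deviation (n − 1) across cells are
reported. The half-radius is the radius where the piecewise-linear
cumulative of the profile reaches 50% — exactly R/2 for a uniform
sharp-edged disk of radius R, less for particles whose density decays at
the periphery.

The localization-based profiles compute each cluster centre as the centre
of mass of the centre-channel localizations within 250 nm of the initial
position, histogram the distances of the profiled channel's localizations
on [0, 200) nm with d = 20 nm, divide by the ring areas
S_j = π(2j − 1)d² (which telescope to the full 200 nm disk), and normalize
to unit sum. For two-colour analysis the centre is always computed from
the CENP-A channel and reused for HJURP, and a stored normalization
coefficient can replace a profile's own (to compare conditions on one
scale, e.g. HJURP late vs early G1). When only image-based sizes are
needed, two documented metrics are exposed (half-radius and the
equivalent-measure diameter of the segmentation) rather than guessing the
unspecified estimator behind published mean-diameter figures.

## Common-line 3D reconstruction

Sinograms are computed by rotate-and-sum with bilinear interpolation after
embedding the image in a √2-sized canvas, so every line conserves the
image mass to < 0.5%. Before correlation, lines are band-pass filtered
(ramp |k| with a Gaussian rolloff at 0.1 of the line length), mean-
subtracted and L2-normalized, and the sinogram is extended to 360° (the
line at θ+180° is the reversed line at θ) so common-line directions keep
their sign. The ramp part suppresses the low-frequency envelope shared by
all directions — without it every line pair correlates near 1 and the
assignment cannot discriminate; the rolloff keeps amplified pixel noise in
check. Images are smoothed with a 1 px Gaussian first (`smoothSigma`).

Angle assignment fixes the gauge with a triplet bootstrap: image 1 is the
identity; the common line with image 1 fixes each of images 2 and 3 up to
the dihedral angle of its projection plane about that line, and the 2–3
common-line correlation scores the (φ₂, φ₃) grid. Because a single
unlucky pair (nearly parallel views, weak common line) would poison
everything downstream, several candidate triplets from the first images
are tried and the most self-consistent kept. Remaining images are placed
sequentially by a coarse ZYZ orientation grid (default 10°) scored by the
sinogram correlation at the predicted common-line angles against up to 12
anchors, refined by Nelder-Mead; further coordinate-descent passes re-grid
every image against all others, which escapes the local optima a purely
sequential assignment can leave behind. The global rotation and the
handedness are fundamentally unresolvable from common lines; the result is
flagged `mirrorAmbiguous` and never silently resolved, and the comparison
helper evaluates angle sets up to a global rotation and mirror
conjugations.

Reconstruction is weighted, filtered back-projection: each image is ramp-
filtered in 2D Fourier space (the exact-filter compensation for the 1/|q|
plane-sampling density), optionally weighted by the inverse local density
of viewing axes (Gaussian kernel of 15°), and smeared through the volume
along its viewing axis with bilinear sampling. Validation re-projects the
volume at the assigned angles and reports per-image Pearson correlations
plus the viewing-axis distribution.

Angular reconstitution needs orientation coverage: with ~10 projections of
a smooth object the assignment can lock into a wrong but self-consistent
configuration, while from ~14 well-spread views upward recovery is stable
(sub-degree on noise-free phantoms, and the method tolerates 10% Gaussian
pixel noise at the 10°-median level). The hollow "rosette" phantom (a
shell with unequal angular lobes) exercises the full pipeline — project,
assign, reconstruct — and retains its interior density dip end to end.

## Problem sizes and runtimes

The test-suite and acceptance runs use desk-scale versions of the study
conditions, chosen to keep every stage honest yet fast: drift recovery on
60 clusters × 1000 molecules (≈ 1.8 × 10⁵ localizations, 10⁴ frames);
profile discrimination on 5 cells × 6 clusters × 500 molecules per
condition; angular reconstitution on 58 projections of a 40³ phantom
(about one minute); the 2D tessellations handle 10⁴–10⁵ points in
seconds. The full suite runs in a few minutes on one CPU.

## Known limitations

* The simulator omits raw-frame effects (PSF shape, camera noise,
  overlapping emitters); conclusions about fitting robustness are out of
  scope.
* The discrete 3D Voronoi is voxel-limited: densities below the voxel
  scale saturate, and adjacency is approximate near cell corners.
* Drift estimation assumes structure-rich fields; sparse fields (< ~10³
  localizations per subset) give noisy anchors, which the per-pass RMS
  diagnostics expose.
* The common-line method presumes the imaged particles share one
  structure; heterogeneity is averaged out, not detected.
* Chromatic correction is lateral (x, y) only; z-dependent chromatic
  fields are not modelled.
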