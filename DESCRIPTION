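Package: CentroSMLM
Title: Single-Molecule Localization Microscopy Analysis of Centromeric
    Protein Clusters
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for single-molecule localization
    microscopy (dSTORM/PALM) studies of centromeric chromatin clusters such as
    CENP-A rosettes. Provides localization-table input/output and histogram
    rendering; drift correction by iterative subset cross-correlation;
    two-colour chromatic-aberration correction with a second-order polynomial
    field; merging of consecutive localizations of the same fluorophore;
    Fourier ring correlation resolution estimation; Voronoi-tessellation
    density mapping and density-threshold cluster segmentation; particle
    picking, normalization and iterative alignment to the rotationally
    averaged sum; per-cell radial-profile statistics, half-radius and
    center-of-mass radial profiles with ring-area correction; and 3D
    reconstruction of a common cluster structure by common-line angular
    reconstitution with weighted, filtered back-projection. A seeded
    synthetic-data generator emulating hollow-shell and filled-sphere
    clusters with blinking, drift, chromatic shift and background makes every
    stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deldir,
    RANN,
    igraph,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Visualization, CellBiology, Software
Collate: 
    'AllClasses.R'
    'CentroSMLM-package.R'
    'accessors.R'
    'chromatic.R'
    'utils-geometry.R'
    'localization-io.R'
    'cluster-analysis.R'
    'drift.R'
    'frc.R'
    'merge.R'
    'voronoi.R'
    'simulate.R'
    'pipeline.R'
    'reconstruction.R'
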