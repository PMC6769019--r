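#' @import methods
NULL

LOC_COLUMNS <- c("id", "frame", "x", "y", "z", "photons", "channel", "sigma")

#' LocalizationTable: a table of single-molecule localizations
#'
#' The universal event list of the pipeline: one row per fitted
#' single-fluorophore event with a 1-based acquisition frame, coordinates in
#' nanometres (z optional), a photon count and a channel index. Every
#' correction stage consumes and produces this class.
#'
#' @slot data data.frame with columns \code{id}, \code{frame}, \code{x},
#'   \code{y}, \code{z}, \code{photons}, \code{channel}, \code{sigma};
#'   additional columns are carried through untouched. \code{z} and
#'   \code{sigma} may be \code{NA}. All distances are nanometres.
#' @export
setClass("LocalizationTable", representation(data = "data.frame"),
         validity = function(object) {
    d <- object@data
    miss <- setdiff(LOC_COLUMNS, names(d))
    if (length(miss))
        return(paste("missing mandatory column(s):", paste(miss, collapse = ", ")))
    if (nrow(d)) {
        if (any(!is.finite(d$frame)) || any(d$frame < 1))
            return("frames must be finite and >= 1")
        if (any(!is.finite(d$x)) || any(!is.finite(d$y)))
            return("x and y must be finite")
        zf <- d$z[!is.na(d$z)]
        if (any(!is.finite(zf))) return("z must be finite or NA")
        if (any(is.na(d$z)) && !all(is.na(d$z)))
            return("z must be present for all localizations or for none")
    }
    TRUE
})

#' Construct a LocalizationTable
#'
#' @param x,y,z coordinates in nm; \code{z = NULL} for 2D data.
#' @param frame 1-based frame numbers (recycled).
#' @param photons photon counts (recycled).
#' @param channel channel indices (recycled).
#' @param id localization ids; default \code{seq_along(x)}.
#' @param sigma optional per-localization precision in nm.
#' @param extras optional data.frame of extra columns carried through I/O.
#' @return A \linkS4class{LocalizationTable}.
#' @export
LocalizationTable <- function(x, y, z = NULL, frame = 1L, photons = 1000,
                              channel = 1L, id = NULL, sigma = NA_real_,
                              extras = NULL) {
    n <- length(x)
    stopifnot(length(y) == n)
    if (is.null(id)) id <- seq_len(n)
    d <- data.frame(id = as.integer(id),
                    frame = as.integer(rep_len(frame, n)),
                    x = as.numeric(x), y = as.numeric(y),
                    z = if (is.null(z)) rep(NA_real_, n) else as.numeric(z),
                    photons = as.numeric(rep_len(photons, n)),
                    channel = as.integer(rep_len(channel, n)),
                    sigma = as.numeric(rep_len(sigma, n)))
    if (!is.null(extras) && ncol(extras)) d <- cbind(d, extras)
    new("LocalizationTable", data = d)
}

#' @describeIn LocalizationTable wrap an existing data.frame (canonical columns)
#' @param data data.frame holding the canonical columns.
#' @export
asLocalizationTable <- function(data) {
    for (col in c("z", "sigma"))
        if (is.null(data[[col]])) data[[col]] <- NA_real_
    if (is.null(data$id)) data$id <- seq_len(nrow(data))
    data <- data[c(LOC_COLUMNS, setdiff(names(data), LOC_COLUMNS))]
    data$id <- as.integer(data$id); data$frame <- as.integer(data$frame)
    data$channel <- as.integer(data$channel)
    rownames(data) <- NULL
    new("LocalizationTable", data = data)
}

#' PixelImage: a rendered 2D image with physical pixel size
#'
#' @slot pixels numeric matrix; the first index is x, the second y. Pixel
#'   (i, j) covers the half-open square
#'   \code{[origin + (i-1) p, origin + i p)} in nm.
#' @slot pixelSize pixel edge in nm.
#' @slot origin nm offset of the image corner, length 2.
#' @export
setClass("PixelImage",
         representation(pixels = "matrix", pixelSize = "numeric", origin = "numeric"),
         validity = function(object) {
    if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
        return("pixelSize must be a single positive number")
    if (length(object@origin) != 2) return("origin must have length 2")
    if (!is.numeric(object@pixels)) return("pixels must be numeric")
    if (any(!is.finite(object@pixels))) return("pixels must be finite")
    TRUE
})

#' @rdname PixelImage-class
#' @param pixels numeric matrix (x by y).
#' @param pixelSize pixel edge in nm.
#' @param origin corner offset in nm.
#' @export
PixelImage <- function(pixels, pixelSize, origin = c(0, 0))
    new("PixelImage", pixels = pixels, pixelSize = as.numeric(pixelSize),
        origin = as.numeric(origin))

#' Volume3D: a reconstruction grid with cubic voxels
#'
#' @slot voxels numeric 3D array.
#' @slot voxelSize voxel edge in nm (cubic voxels).
#' @slot origin nm offset of the volume corner, length 3.
#' @export
setClass("Volume3D",
         representation(voxels = "array", voxelSize = "numeric", origin = "numeric"),
         validity = function(object) {
    if (length(dim(object@voxels)) != 3) return("voxels must be a 3D array")
    if (length(object@voxelSize) != 1 || object@voxelSize <= 0)
        return("voxelSize must be a single positive number")
    if (length(object@origin) != 3) return("origin must have length 3")
    if (any(!is.finite(object@voxels))) return("voxels must be finite")
    TRUE
})

#' @rdname Volume3D-class
#' @param voxels numeric 3D array.
#' @param voxelSize voxel edge in nm.
#' @param origin corner offset in nm.
#' @export
Volume3D <- function(voxels, voxelSize, origin = c(0, 0, 0))
    new("Volume3D", voxels = voxels, voxelSize = as.numeric(voxelSize),
        origin = as.numeric(origin))

#' DriftTrajectory: per-frame stage drift
#'
#' Shift vectors (nm) for every acquisition frame, obtained by linear
#' interpolation between subset anchor frames. The shift at the reference
#' subset is zero by construction.
#'
#' @slot shifts numeric matrix, one row per frame, 2 (x, y) or 3 (x, y, z)
#'   columns, in nm.
#' @export
setClass("DriftTrajectory", representation(shifts = "matrix"),
         validity = function(object) {
    if (!ncol(object@shifts) %in% c(2, 3)) return("shifts must have 2 or 3 columns")
    if (any(!is.finite(object@shifts))) return("shifts must be finite")
    TRUE
})

#' @rdname DriftTrajectory-class
#' @param shifts per-frame shift matrix in nm (rows = frames 1..n).
#' @export
DriftTrajectory <- function(shifts) {
    shifts <- as.matrix(shifts)
    colnames(shifts) <- c("dx", "dy", "dz")[seq_len(ncol(shifts))]
    new("DriftTrajectory", shifts = shifts)
}

#' ChromaticModel: polynomial chromatic-aberration field
#'
#' A full second-order bivariate polynomial in (x, y) per axis describing the
#' shift of the non-reference channel relative to the reference channel.
#'
#' @slot coefficients 6 x 2 numeric matrix; rows are the monomials
#'   \code{1, x, y, x^2, xy, y^2}, columns the shift components (dx, dy) in nm
#'   (coordinates in nm).
#' @slot referenceChannel channel whose coordinates are left untouched.
#' @export
setClass("ChromaticModel",
         representation(coefficients = "matrix", referenceChannel = "integer"),
         validity = function(object) {
    if (!all(dim(object@coefficients) == c(6, 2)))
        return("coefficients must be a 6 x 2 matrix")
    if (any(!is.finite(object@coefficients))) return("coefficients must be finite")
    TRUE
})

#' @rdname ChromaticModel-class
#' @param coefficients 6 x 2 matrix (monomials 1, x, y, x^2, xy, y^2).
#' @param referenceChannel reference channel id.
#' @export
ChromaticModel <- function(coefficients = matrix(0, 6, 2), referenceChannel = 1L) {
    coefficients <- as.matrix(coefficients)
    rownames(coefficients) <- c("1", "x", "y", "x2", "xy", "y2")
    colnames(coefficients) <- c("dx", "dy")
    new("ChromaticModel", coefficients = coefficients,
        referenceChannel = as.integer(referenceChannel))
}

setClassUnion("DriftTrajectoryOrNULL", c("DriftTrajectory", "NULL"))
setClassUnion("ChromaticModelOrNULL", c("ChromaticModel", "NULL"))

#' ClusterModel: geometric model of one cluster
#'
#' Ground-truth geometry for the synthetic-data generator. A \code{shell} is a
#' uniform spherical shell between inner and outer radius (the rosette-like
#' early-G1 cluster); \code{filled} is an isotropic Gaussian ball with
#' FWHM = outerDiameter / 2 (the compact late-G1 cluster); \code{disk} is a
#' flat cylinder (the mitotic plate-like cluster).
#'
#' @slot kind "shell", "filled" or "disk".
#' @slot outerDiameter outer diameter in nm.
#' @slot innerDiameter inner (cavity) diameter in nm; shells only, stored as 0
#'   for other kinds.
#' @slot nMolecules number of fluorophore-carrying molecules.
#' @slot subclusterCount number of angular density lobes (0 = isotropic).
#' @slot center cluster center, nm, length 3.
#' @export
setClass("ClusterModel",
         representation(kind = "character", outerDiameter = "numeric",
                        innerDiameter = "numeric", nMolecules = "integer",
                        subclusterCount = "integer", center = "numeric",
                        channel = "integer"),
         validity = function(object) {
    if (!object@kind %in% c("shell", "filled", "disk"))
        return("kind must be one of shell, filled, disk")
    if (object@nMolecules < 1) return("nMolecules must be >= 1")
    if (object@kind == "shell" && object@innerDiameter >= object@outerDiameter)
        return("innerDiameter must be smaller than outerDiameter")
    if (length(object@center) != 3) return("center must have length 3")
    TRUE
})

#' @rdname ClusterModel-class
#' @param kind "shell", "filled" or "disk".
#' @param outerDiameter outer diameter, nm (default 280, within the observed
#'   250--300 nm range of rosette clusters).
#' @param innerDiameter cavity diameter, nm (default 100; shells only).
#' @param nMolecules molecules in the cluster.
#' @param subclusterCount angular density lobes, 0 for isotropic.
#' @param center 3-vector, nm.
#' @param channel imaging channel the cluster's molecules emit in.
#' @export
ClusterModel <- function(kind = c("shell", "filled", "disk"),
                         outerDiameter = 280, innerDiameter = 100,
                         nMolecules = 500L, subclusterCount = 0L,
                         center = c(0, 0, 0), channel = 1L) {
    kind <- match.arg(kind)
    if (kind != "shell") innerDiameter <- 0
    new("ClusterModel", kind = kind, outerDiameter = as.numeric(outerDiameter),
        innerDiameter = as.numeric(innerDiameter),
        nMolecules = as.integer(nMolecules),
        subclusterCount = as.integer(subclusterCount),
        center = as.numeric(center), channel = as.integer(channel))
}

#' AcquisitionModel: SMLM acquisition parameters for the simulator
#'
#' @slot nFrames number of camera frames.
#' @slot meanOnFrames expected consecutive emitting frames per molecule
#'   (geometric run length).
#' @slot locPrecision localization precision sigma in nm, length 2
#'   (lateral, axial).
#' @slot meanPhotons expected photons per localization.
#' @slot backgroundDensity background localizations per square micrometre per
#'   frame.
#' @slot fieldSize field extent in nm, length 2 or 3.
#' @slot drift optional true \linkS4class{DriftTrajectory}.
#' @slot chromatic optional true \linkS4class{ChromaticModel} applied to
#'   channel-2 localizations.
#' @slot seed integer seed; identical seeds give bit-identical tables.
#' @export
setClass("AcquisitionModel",
         representation(nFrames = "integer", meanOnFrames = "numeric",
                        locPrecision = "numeric", meanPhotons = "numeric",
                        backgroundDensity = "numeric", fieldSize = "numeric",
                        drift = "DriftTrajectoryOrNULL",
                        chromatic = "ChromaticModelOrNULL", seed = "integer"),
         validity = function(object) {
    if (object@nFrames < 1) return("nFrames must be >= 1")
    if (object@meanOnFrames < 1) return("meanOnFrames must be >= 1")
    if (any(object@locPrecision < 0)) return("locPrecision must be >= 0")
    if (object@meanPhotons < 0 || object@backgroundDensity < 0)
        return("rates must be >= 0")
    if (!length(object@fieldSize) %in% c(2, 3) || any(object@fieldSize <= 0))
        return("fieldSize must be 2 or 3 positive extents in nm")
    TRUE
})

#' @rdname AcquisitionModel-class
#' @param nFrames camera frames (default 15000).
#' @param meanOnFrames mean consecutive emitting frames (default 3).
#' @param locPrecision sigma nm; one value (isotropic) or c(lateral, axial).
#' @param meanPhotons mean photons per localization.
#' @param backgroundDensity background localizations per um^2 per frame.
#' @param fieldSize field extent nm, length 2 or 3.
#' @param drift optional DriftTrajectory.
#' @param chromatic optional ChromaticModel.
#' @param seed integer seed.
#' @export
AcquisitionModel <- function(nFrames = 15000L, meanOnFrames = 3,
                             locPrecision = c(10, 25), meanPhotons = 1000,
                             backgroundDensity = 1e-3,
                             fieldSize = c(2000, 2000, 1000),
                             drift = NULL, chromatic = NULL, seed = 1L) {
    if (length(locPrecision) == 1) locPrecision <- c(locPrecision, locPrecision)
    new("AcquisitionModel", nFrames = as.integer(nFrames),
        meanOnFrames = as.numeric(meanOnFrames),
        locPrecision = as.numeric(locPrecision),
        meanPhotons = as.numeric(meanPhotons),
        backgroundDensity = as.numeric(backgroundDensity),
        fieldSize = as.numeric(fieldSize), drift = drift,
        chromatic = chromatic, seed = as.integer(seed))
}

#' EulerAngleSet: per-image orientation assignment
#'
#' ZYZ Euler angles (degrees) per projection image. The global orientation and
#' the handedness (mirror) of a common-line assignment are not determined by
#' the data; \code{mirrorAmbiguous} records this.
#'
#' @slot angles n x 3 matrix, columns alpha, beta, gamma in degrees.
#' @slot convention Euler convention, always "ZYZ".
#' @slot mirrorAmbiguous TRUE when the set stems from common lines and is
#'   defined only up to a global mirror.
#' @export
setClass("EulerAngleSet",
         representation(angles = "matrix", convention = "character",
                        mirrorAmbiguous = "logical"),
         validity = function(object) {
    if (ncol(object@angles) != 3) return("angles must have 3 columns")
    if (any(!is.finite(object@angles))) return("angles must be finite")
    if (object@convention != "ZYZ") return("only the ZYZ convention is supported")
    TRUE
})

#' @rdname EulerAngleSet-class
#' @param angles n x 3 matrix (alpha, beta, gamma, degrees).
#' @param mirrorAmbiguous logical flag.
#' @export
EulerAngleSet <- function(angles, mirrorAmbiguous = FALSE) {
    angles <- as.matrix(angles)
    colnames(angles) <- c("alpha", "beta", "gamma")
    new("EulerAngleSet", angles = angles, convention = "ZYZ",
        mirrorAmbiguous = mirrorAmbiguous)
}

#' GroundTruth: simulator ground truth
#'
#' @slot molecules n x 3 matrix of true molecule positions (nm).
#' @slot moleculeId per-localization molecule id; NA for background events.
#' @slot models list of \linkS4class{ClusterModel}.
#' @slot drift true drift or NULL.
#' @slot chromatic true chromatic model or NULL.
#' @slot angles true projection angles (for phantom stacks) or NULL.
#' @export
setClass("GroundTruth",
         representation(molecules = "matrix", moleculeId = "integer",
                        models = "list", drift = "DriftTrajectoryOrNULL",
                        chromatic = "ChromaticModelOrNULL", angles = "ANY"))

#' VoronoiDensity: per-localization Voronoi densities
#'
#' @slot stats data.frame with per-localization columns \code{measure} (cell
#'   area nm^2 or volume nm^3), \code{density} (1/measure),
#'   \code{densityAvg} (first-rank average of 1/measure over the cell and its
#'   Delaunay neighbours) and \code{finite} (FALSE for unbounded border cells).
#' @slot edges 2-column integer matrix of Delaunay adjacency.
#' @slot dims 2 or 3.
#' @export
setClass("VoronoiDensity",
         representation(stats = "data.frame", edges = "matrix", dims = "integer"))

#' SegmentationResult: density-threshold cluster segmentation
#'
#' @slot labels integer per localization; 0 = background.
#' @slot clusters data.frame with one row per cluster: label, n, centroid
#'   coordinates and equivalent diameter (nm).
#' @slot threshold the density threshold used (nm^-2 or nm^-3).
#' @export
setClass("SegmentationResult",
         representation(labels = "integer", clusters = "data.frame",
                        threshold = "numeric"))

#' ClusterStack: boxed cluster images with alignment transforms
#'
#' @slot images list of square numeric matrices, identical dimensions.
#' @slot pixelSize pixel edge, nm.
#' @slot info data.frame, one row per image: \code{cell}, \code{cluster},
#'   \code{dx}, \code{dy} (applied shift, px), \code{rotation} (deg),
#'   \code{normalized}.
#' @export
setClass("ClusterStack",
         representation(images = "list", pixelSize = "numeric", info = "data.frame"),
         validity = function(object) {
    if (length(object@images)) {
        d <- dim(object@images[[1]])
        if (d[1] != d[2]) return("cluster boxes must be square")
        same <- vapply(object@images, function(m) all(dim(m) == d), logical(1))
        if (!all(same)) return("all boxes must have identical dimensions")
    }
    if (nrow(object@info) != length(object@images))
        return("info must have one row per image")
    TRUE
})

#' @rdname ClusterStack-class
#' @param images list of square matrices.
#' @param pixelSize pixel edge, nm.
#' @param info per-image metadata; defaults are filled in.
#' @export
ClusterStack <- function(images, pixelSize, info = NULL) {
    n <- length(images)
    if (is.null(info))
        info <- data.frame(cell = rep(1L, n), cluster = seq_len(n),
                           dx = 0, dy = 0, rotation = 0, normalized = FALSE)
    new("ClusterStack", images = images, pixelSize = as.numeric(pixelSize),
        info = info)
}

#' RadialProfile: binned radial density profile
#'
#' Radial profiles use half-open bins \code{[jd - d, jd)} of width \code{d}.
#' For localization histograms the raw counts are divided by the ring surface
#' areas \code{S_j = pi (2j - 1) d^2} to give a density comparable across
#' radii, then normalized to unit sum.
#'
#' @slot binWidth bin width d in nm.
#' @slot binCenters bin centers in nm.
#' @slot raw raw profile (counts, or ring-mean intensity for image profiles).
#' @slot density area-corrected profile.
#' @slot normalized density scaled so that its sum is 1 (or scaled by an
#'   externally supplied normalization coefficient).
#' @slot perCell matrix of per-cell normalized profiles (cells x bins), may be
#'   empty.
#' @slot mean,sd pointwise mean and sample standard deviation across cells.
#' @export
setClass("RadialProfile",
         representation(binWidth = "numeric", binCenters = "numeric",
                        raw = "numeric", density = "numeric",
                        normalized = "numeric", perCell = "matrix",
                        mean = "numeric", sd = "numeric"))

#' Sinogram: Radon transform of one image
#'
#' Line projections of a square image over in-plane angles \code{[0, 180)} at
#' a fixed angular step. Each line conserves the image's total mass.
#'
#' @slot lines matrix (angles x positions).
#' @slot angularStep angular step, degrees.
#' @slot angles the angles (deg) of the rows.
#' @export
setClass("Sinogram",
         representation(lines = "matrix", angularStep = "numeric",
                        angles = "numeric"))
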