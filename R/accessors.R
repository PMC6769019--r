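#' @include AllClasses.R
NULL

#' Accessors for LocalizationTable
#'
#' @param x a \linkS4class{LocalizationTable}.
#' @return \code{locData} the underlying data.frame; \code{locCoords} an
#'   n x dims coordinate matrix (nm); \code{locDims} 2 or 3; \code{locFrames},
#'   \code{locChannels}, \code{locPhotons} the respective columns.
#' @export
locData <- function(x) x@data

#' @rdname locData
#' @export
locDims <- function(x) if (all(is.na(x@data$z))) 2L else 3L

#' @rdname locData
#' @export
locCoords <- function(x) {
    d <- x@data
    if (locDims(x) == 2L) cbind(x = d$x, y = d$y)
    else cbind(x = d$x, y = d$y, z = d$z)
}

#' @rdname locData
#' @export
locFrames <- function(x) x@data$frame

#' @rdname locData
#' @export
locChannels <- function(x) x@data$channel

#' @rdname locData
#' @export
locPhotons <- function(x) x@data$photons

#' @describeIn locData number of localizations
#' @export
setMethod("length", "LocalizationTable", function(x) nrow(x@data))

#' Subset a LocalizationTable by row
#' @param x a LocalizationTable.
#' @param i row index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "LocalizationTable", function(x, i, j, ..., drop = FALSE) {
    d <- x@data[i, , drop = FALSE]
    rownames(d) <- NULL
    new("LocalizationTable", data = d)
})

setMethod("show", "LocalizationTable", function(object) {
    d <- object@data
    cat(sprintf("LocalizationTable: %d localizations (%dD), %d channel(s), frames %s\n",
                nrow(d), locDims(object), length(unique(d$channel)),
                if (nrow(d)) paste(range(d$frame), collapse = "..") else "-"))
    if (nrow(d)) print(utils::head(d, 4L))
})

#' Accessors for PixelImage and Volume3D
#' @param x a \linkS4class{PixelImage} or \linkS4class{Volume3D}.
#' @return the pixel/voxel array, the pixel/voxel size (nm), or the origin (nm).
#' @export
pixelData <- function(x) x@pixels

#' @rdname pixelData
#' @export
pixelSize <- function(x) if (is(x, "Volume3D")) x@voxelSize else x@pixelSize

#' @rdname pixelData
#' @export
voxelData <- function(x) x@voxels

#' @rdname pixelData
#' @export
imageOrigin <- function(x) x@origin

setMethod("show", "PixelImage", function(object) {
    cat(sprintf("PixelImage: %d x %d px, %.3g nm/px, origin (%.4g, %.4g) nm, sum %.6g\n",
                nrow(object@pixels), ncol(object@pixels), object@pixelSize,
                object@origin[1], object@origin[2], sum(object@pixels)))
})

setMethod("show", "Volume3D", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("Volume3D: %d x %d x %d voxels, %.3g nm/voxel, max %.6g\n",
                d[1], d[2], d[3], object@voxelSize, max(object@voxels)))
})

setMethod("dim", "PixelImage", function(x) dim(x@pixels))
setMethod("dim", "Volume3D", function(x) dim(x@voxels))

#' Accessors for DriftTrajectory
#' @param x a \linkS4class{DriftTrajectory}.
#' @return \code{driftShifts} the frames x dims shift matrix (nm);
#'   \code{nFrames} its number of frames.
#' @export
driftShifts <- function(x) x@shifts

#' @rdname driftShifts
#' @export
nFrames <- function(x) nrow(x@shifts)

setMethod("show", "DriftTrajectory", function(object) {
    cat(sprintf("DriftTrajectory: %d frames, %dD, max |shift| %.2f nm\n",
                nrow(object@shifts), ncol(object@shifts),
                if (nrow(object@shifts)) max(abs(object@shifts)) else 0))
})

#' Accessors for ChromaticModel
#' @param x a \linkS4class{ChromaticModel}.
#' @return the 6 x 2 coefficient matrix or the reference channel id.
#' @export
chromaticCoefficients <- function(x) x@coefficients

#' @rdname chromaticCoefficients
#' @export
referenceChannel <- function(x) x@referenceChannel

setMethod("show", "ChromaticModel", function(object) {
    cat(sprintf("ChromaticModel: 2nd-order polynomial shift field, reference channel %d\n",
                object@referenceChannel))
    print(signif(object@coefficients, 4))
})

#' Accessors for VoronoiDensity and SegmentationResult
#' @param x a \linkS4class{VoronoiDensity} or \linkS4class{SegmentationResult}.
#' @return per-localization density statistics, Delaunay edges, cluster labels
#'   or the per-cluster summary table.
#' @export
densityStats <- function(x) x@stats

#' @rdname densityStats
#' @export
delaunayEdges <- function(x) x@edges

#' @rdname densityStats
#' @export
clusterLabels <- function(x) x@labels

#' @rdname densityStats
#' @export
clusterTable <- function(x) x@clusters

setMethod("show", "VoronoiDensity", function(object) {
    cat(sprintf("VoronoiDensity: %d localizations (%dD), %d finite cells, %d Delaunay edges\n",
                nrow(object@stats), object@dims, sum(object@stats$finite),
                nrow(object@edges)))
})

setMethod("show", "SegmentationResult", function(object) {
    cat(sprintf("SegmentationResult: %d cluster(s), %d of %d localizations assigned (threshold %.3g)\n",
                nrow(object@clusters), sum(object@labels > 0),
                length(object@labels), object@threshold))
})

#' Accessors for ClusterStack
#' @param x a \linkS4class{ClusterStack}.
#' @return the image list, the per-image metadata, or the box edge in pixels.
#' @export
stackImages <- function(x) x@images

#' @rdname stackImages
#' @export
stackInfo <- function(x) x@info

#' @rdname stackImages
#' @export
boxSizePx <- function(x) if (length(x@images)) nrow(x@images[[1]]) else 0L

#' @describeIn stackImages number of images in the stack
#' @export
setMethod("length", "ClusterStack", function(x) length(x@images))

setMethod("show", "ClusterStack", function(object) {
    cat(sprintf("ClusterStack: %d image(s), %d x %d px at %.3g nm/px, %d cell(s)\n",
                length(object@images), boxSizePx(object), boxSizePx(object),
                object@pixelSize, length(unique(object@info$cell))))
})

#' Accessors for RadialProfile
#' @param x a \linkS4class{RadialProfile}.
#' @return bin centers (nm), the area-corrected density trace, the normalized
#'   profile, the per-cell profile matrix, or the cross-cell mean/sd.
#' @export
profileBins <- function(x) x@binCenters

#' @rdname profileBins
#' @export
profileDensity <- function(x) x@density

#' @rdname profileBins
#' @export
profileNormalized <- function(x) x@normalized

#' @rdname profileBins
#' @export
profilePerCell <- function(x) x@perCell

#' @rdname profileBins
#' @export
profileMean <- function(x) x@mean

#' @rdname profileBins
#' @export
profileSd <- function(x) x@sd

setMethod("show", "RadialProfile", function(object) {
    cat(sprintf("RadialProfile: %d bins of %.3g nm over [0, %.4g) nm",
                length(object@binCenters), object@binWidth,
                object@binWidth * length(object@binCenters)))
    if (nrow(object@perCell)) cat(sprintf(", %d cell(s)", nrow(object@perCell)))
    cat("\n")
})

#' Accessors for EulerAngleSet and Sinogram
#' @param x an \linkS4class{EulerAngleSet} or \linkS4class{Sinogram}.
#' @return the angle matrix (degrees) or the sinogram line matrix.
#' @export
eulerAngles <- function(x) x@angles

#' @rdname eulerAngles
#' @export
sinogramLines <- function(x) x@lines

setMethod("show", "EulerAngleSet", function(object) {
    cat(sprintf("EulerAngleSet: %d image(s), ZYZ degrees%s\n", nrow(object@angles),
                if (object@mirrorAmbiguous) " (global rotation/mirror undetermined)" else ""))
})

setMethod("show", "Sinogram", function(object) {
    cat(sprintf("Sinogram: %d lines of %d samples, %.3g deg step\n",
                nrow(object@lines), ncol(object@lines), object@angularStep))
})

#' Accessors for GroundTruth
#' @param x a \linkS4class{GroundTruth}.
#' @return true molecule positions, per-localization molecule ids, the cluster
#'   models, or the true drift trajectory.
#' @export
trueMolecules <- function(x) x@molecules

#' @rdname trueMolecules
#' @export
moleculeIds <- function(x) x@moleculeId

#' @rdname trueMolecules
#' @export
trueModels <- function(x) x@models

#' @rdname trueMolecules
#' @export
trueDrift <- function(x) x@drift

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %d molecules, %d cluster model(s), %d localization ids\n",
                nrow(object@molecules), length(object@models),
                length(object@moleculeId)))
})
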