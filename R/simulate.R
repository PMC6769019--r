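#' @include AllClasses.R accessors.R utils-geometry.R
NULL

## Draw n true molecule positions (nm, relative to the cluster center) on the
## support of a ClusterModel. The support follows the imaging dimensionality:
## in 3D a shell is a uniform spherical shell between the radii, in 2D it is
## the annular ring seen in projection imaging of ring-like clusters.
sampleModelPositions <- function(model, n, dims = 3) {
    ro <- model@outerDiameter / 2
    ri <- model@innerDiameter / 2
    if (model@kind == "filled") {
        sigma <- (model@outerDiameter / 2) / (2 * sqrt(2 * log(2)))
        p <- matrix(stats::rnorm(3 * n, 0, sigma), n, 3)
        if (dims == 2) p[, 3] <- 0
    } else if (model@kind == "disk") {
        r <- ro * sqrt(stats::runif(n))
        th <- stats::runif(n, 0, 2 * pi)
        h <- model@outerDiameter / 5   # flat cylinder thickness
        z <- if (dims == 2) 0 else stats::runif(n, -h / 2, h / 2)
        p <- cbind(r * cos(th), r * sin(th), z)
    } else {                           # shell: uniform between radii
        keep <- matrix(numeric(0), 0, 3)
        m <- model@subclusterCount
        while (nrow(keep) < n) {
            k <- n - nrow(keep)
            u <- stats::runif(k)
            phi <- stats::runif(k, 0, 2 * pi)
            if (dims == 2) {           # annular ring, uniform in area
                r <- sqrt(u * (ro^2 - ri^2) + ri^2)
                pts <- cbind(r * cos(phi), r * sin(phi), 0)
            } else {                   # spherical shell, uniform in volume
                r <- (u * (ro^3 - ri^3) + ri^3)^(1 / 3)
                v <- stats::runif(k, -1, 1)          # cos(polar)
                s <- sqrt(1 - v^2)
                pts <- cbind(r * s * cos(phi), r * s * sin(phi), r * v)
            }
            if (m > 0) {
                # raised-cosine azimuthal lobes emulate sub-clustering
                w <- (1 + cos(m * phi)) / 2
                pts <- pts[stats::runif(k) < w, , drop = FALSE]
            }
            keep <- rbind(keep, pts)
        }
        p <- keep[seq_len(n), , drop = FALSE]
    }
    sweep(p, 2, model@center, "+")
}

#' Simulate an SMLM acquisition of a field of clusters
#'
#' Generates a seeded localization table with known ground truth. Molecules
#' are drawn uniformly on each cluster model's support (for shells: a uniform
#' spherical shell between the radii in 3D, the corresponding annular ring
#' for 2D projection imaging); each molecule emits in
#' one run of consecutive frames whose length is geometric with mean
#' \code{meanOnFrames}; every emitting frame yields one localization equal to
#' the true position plus the frame's drift, Gaussian localization error and
#' (channel 2 only) the chromatic shift. Uniform background localizations are
#' added over the field. The table is sorted by frame and the same seed gives
#' a bit-identical table.
#'
#' @param models non-empty list of \linkS4class{ClusterModel}.
#' @param acq an \linkS4class{AcquisitionModel}.
#' @param dims 2 or 3; with \code{dims = 2} the z coordinate is dropped
#'   (projection imaging) and axial drift is rejected.
#' @return list with elements \code{table} (\linkS4class{LocalizationTable})
#'   and \code{truth} (\linkS4class{GroundTruth}).
#' @export
simulateField <- function(models, acq, dims = 2) {
    if (!length(models)) stop("'models' must be a non-empty list of ClusterModel")
    if (is(models, "ClusterModel")) models <- list(models)
    stopifnot(dims %in% c(2, 3))
    if (dims == 2 && !is.null(acq@drift) && ncol(driftShifts(acq@drift)) == 3)
        stop("axial drift is not meaningful for dims = 2")
    field <- acq@fieldSize
    if (length(field) == 2) field <- c(field, field[1] / 2)
    withSeed(acq@seed, {
        pos <- lapply(models, function(m)
            sampleModelPositions(m, m@nMolecules, dims))
        molPos <- do.call(rbind, pos)
        molChannel <- rep(vapply(models, function(m) m@channel, integer(1)),
                          vapply(models, function(m) m@nMolecules, integer(1)))
        nMol <- nrow(molPos)
        runLen <- 1L + stats::rgeom(nMol, prob = 1 / acq@meanOnFrames)
        runStart <- sample.int(acq@nFrames, nMol, replace = TRUE)
        runLen <- pmin(runLen, acq@nFrames - runStart + 1L)
        molIdx <- rep.int(seq_len(nMol), runLen)
        frame <- runStart[molIdx] + sequence(runLen) - 1L
        n <- length(frame)
        sig <- acq@locPrecision
        x <- molPos[molIdx, 1] + stats::rnorm(n, 0, sig[1])
        y <- molPos[molIdx, 2] + stats::rnorm(n, 0, sig[1])
        z <- molPos[molIdx, 3] + stats::rnorm(n, 0, sig[2])
        channel <- molChannel[molIdx]
        molId <- molIdx
        # background: uniform over the field, Poisson count per acquisition
        areaUm2 <- prod(field[1:2]) / 1e6
        nBg <- stats::rpois(1, acq@backgroundDensity * areaUm2 * acq@nFrames)
        if (nBg > 0) {
            x <- c(x, stats::runif(nBg, 0, field[1]))
            y <- c(y, stats::runif(nBg, 0, field[2]))
            z <- c(z, stats::runif(nBg, 0, field[3]))
            frame <- c(frame, sample.int(acq@nFrames, nBg, replace = TRUE))
            channel <- c(channel, rep(1L, nBg))
            molId <- c(molId, rep(NA_integer_, nBg))
        }
        n <- length(x)
        if (!is.null(acq@drift)) {
            sh <- driftShifts(acq@drift)
            x <- x + sh[frame, 1]
            y <- y + sh[frame, 2]
            if (ncol(sh) == 3) z <- z + sh[frame, 3]
        }
        if (!is.null(acq@chromatic)) {
            ch2 <- channel != referenceChannel(acq@chromatic)
            if (any(ch2)) {
                shift <- evalChromatic(acq@chromatic, x[ch2], y[ch2])
                x[ch2] <- x[ch2] + shift[, 1]
                y[ch2] <- y[ch2] + shift[, 2]
            }
        }
        photons <- stats::rpois(n, acq@meanPhotons)
        ord <- order(frame)
        tab <- LocalizationTable(x = x[ord], y = y[ord],
                                 z = if (dims == 3) z[ord] else NULL,
                                 frame = frame[ord], photons = photons[ord],
                                 channel = channel[ord], sigma = sig[1])
        truth <- new("GroundTruth", molecules = molPos,
                     moleculeId = as.integer(molId[ord]), models = models,
                     drift = acq@drift, chromatic = acq@chromatic,
                     angles = NULL)
        list(table = tab, truth = truth)
    })
}

#' Simulate a two-channel bead calibration field
#'
#' Emulates multicolour fiducial beads (e.g. 0.2 um TetraSpeck microspheres)
#' used to calibrate chromatic aberration: channel-2 positions equal channel-1
#' positions plus the polynomial chromatic shift plus Gaussian noise. Bead
#' pairing is retained through shared ids.
#'
#' @param nBeads number of beads; at least 6, since the per-axis 2nd-order
#'   bivariate polynomial has 6 coefficients.
#' @param field field extent nm, length 2.
#' @param chromatic a \linkS4class{ChromaticModel} (the true aberration).
#' @param sigma localization noise sigma in nm.
#' @param seed integer seed.
#' @return A two-channel \linkS4class{LocalizationTable}; bead ids pair the
#'   channels.
#' @export
simulateBeads <- function(nBeads, field = c(20000, 20000), chromatic,
                          sigma = 1, seed = 1L) {
    if (nBeads < 6)
        stop("nBeads must be >= 6: the 2nd-order polynomial fit has 6 ",
             "coefficients per axis and would be underdetermined")
    withSeed(seed, {
        x1 <- stats::runif(nBeads, 0, field[1])
        y1 <- stats::runif(nBeads, 0, field[2])
        shift <- evalChromatic(chromatic, x1, y1)
        x2 <- x1 + shift[, 1] + stats::rnorm(nBeads, 0, sigma)
        y2 <- y1 + shift[, 2] + stats::rnorm(nBeads, 0, sigma)
        LocalizationTable(x = c(x1, x2), y = c(y1, y2), frame = 1L,
                          photons = 5000, channel = rep(1:2, each = nBeads),
                          id = rep(seq_len(nBeads), 2), sigma = sigma)
    })
}

#' Build a synthetic phantom volume
#'
#' Soft-edged density phantoms used to exercise projection and 3D
#' reconstruction: a hollow spherical shell (outer diameter 280 nm, cavity
#' 100 nm by default, matching rosette-like clusters), a filled Gaussian ball,
#' or an asymmetric (C1) multi-blob object for angular-recovery tests.
#'
#' @param kind "shell", "filled", "asymmetric" or "rosette" (a hollow shell
#'   with unequal angular lobes: shell geometry with the sub-structure that
#'   makes common-line angle assignment non-degenerate).
#' @param n cubic grid size in voxels.
#' @param voxelSize voxel edge, nm.
#' @param outerDiameter,innerDiameter shell geometry, nm.
#' @return A \linkS4class{Volume3D}.
#' @export
phantomVolume <- function(kind = c("shell", "filled", "asymmetric", "rosette"),
                          n = 48, voxelSize = 8, outerDiameter = 280,
                          innerDiameter = 100) {
    kind <- match.arg(kind)
    c0 <- (n + 1) / 2
    ax <- (seq_len(n) - c0) * voxelSize
    g <- expand.grid(x = ax, y = ax, z = ax)
    r <- sqrt(g$x^2 + g$y^2 + g$z^2)
    edge <- voxelSize            # soft edge width
    softBall <- function(r, R) 1 / (1 + exp((r - R) / edge))
    v <- switch(kind,
        shell = softBall(r, outerDiameter / 2) -
                softBall(r, innerDiameter / 2),
        rosette = {
            # pronounced, unequal angular lobes: rosette-like clusters show
            # discrete sub-clusters, and the lobes must break the rotational
            # symmetry strongly enough for common lines to discriminate
            phi <- atan2(g$y, g$x)
            cth <- ifelse(r > 0, g$z / r, 0)
            lobes <- 1 + 0.60 * cos(phi) + 0.50 * cos(2 * phi + 1) +
                     0.40 * cos(3 * phi + 2.1) + 0.50 * cth +
                     0.4 * cth * cos(phi + 0.5)
            (softBall(r, outerDiameter / 2) - softBall(r, innerDiameter / 2)) *
                pmax(lobes, 0.05)
        },
        filled = {
            sigma <- (outerDiameter / 2) / (2 * sqrt(2 * log(2)))
            exp(-r^2 / (2 * sigma^2))
        },
        asymmetric = {
            blob <- function(cx, cy, cz, s, a) {
                a * exp(-((g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2) / (2 * s^2))
            }
            R <- outerDiameter / 2
            blob(0.45 * R, 0.1 * R, -0.2 * R, 0.30 * R, 1.0) +
            blob(-0.5 * R, 0.35 * R, 0.25 * R, 0.22 * R, 0.8) +
            blob(-0.1 * R, -0.55 * R, 0.45 * R, 0.18 * R, 0.6) +
            blob(0.15 * R, 0.5 * R, 0.55 * R, 0.14 * R, 0.5)
        })
    Volume3D(array(v, c(n, n, n)), voxelSize)
}

#' Project a phantom volume at given orientations
#'
#' Parallel-beam line-integral projections: image k is the integral of the
#' volume along the viewing axis of its ZYZ Euler orientation. Used to test
#' the 3D reconstruction against known angles.
#'
#' @param volume a cubic \linkS4class{Volume3D}.
#' @param angles an \linkS4class{EulerAngleSet}.
#' @return A \linkS4class{ClusterStack} of projections (pixel size = voxel
#'   size).
#' @export
projectPhantom <- function(volume, angles) {
    d <- dim(voxelData(volume))
    if (length(unique(d)) != 1) stop("phantom volume must be cubic")
    imgs <- lapply(seq_len(nrow(eulerAngles(angles))), function(k) {
        projectVolumeImage(volume, eulerAngles(angles)[k, ])
    })
    ClusterStack(imgs, pixelSize = pixelSize(volume))
}

#' Generate pseudo-random Euler angles with good sphere coverage
#'
#' @param n number of orientations.
#' @param seed integer seed.
#' @return An \linkS4class{EulerAngleSet} with alpha, gamma uniform in
#'   [0, 360) and cos(beta) uniform in [-1, 1].
#' @export
randomEulerAngles <- function(n, seed = 1L) {
    withSeed(seed, {
        EulerAngleSet(cbind(alpha = stats::runif(n, 0, 360),
                            beta = acos(stats::runif(n, -1, 1)) * 180 / pi,
                            gamma = stats::runif(n, 0, 360)))
    })
}
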