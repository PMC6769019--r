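#' @include AllClasses.R accessors.R localization-io.R utils-geometry.R
NULL

#' Pick cluster windows from an image or localization table
#'
#' Extracts square windows centred on cluster positions, either supplied
#' (manual picking) or detected automatically as local maxima of a
#' Gaussian-smoothed rendering above an intensity percentile.
#'
#' @param x a \linkS4class{PixelImage}, or a \linkS4class{LocalizationTable}
#'   which is rendered at \code{pixelSize}.
#' @param centers optional n x 2 matrix of cluster centres in nm; \code{NULL}
#'   selects automatic detection.
#' @param box box edge in nm (default 500).
#' @param pixelSize rendering pixel size when \code{x} is a table (default 20).
#' @param channel optional channel filter for rendering.
#' @param cell cell id stored with every picked window.
#' @param smoothSigma Gaussian sigma (nm) for the detection smoothing;
#'   the default 100 nm emulates peak detection in the diffraction-limited
#'   (low-resolution) fluorescence image, which places the peak at the centre
#'   of ring-like clusters rather than on their crest.
#' @param percentile intensity percentile above which peaks are considered.
#' @param minSeparation minimum distance between detected centres, nm.
#' @return A \linkS4class{ClusterStack}; \code{stackInfo} carries the window
#'   centres (\code{cx}, \code{cy}, nm). Windows that would cross the image
#'   border are skipped with a warning.
#' @export
pickClusters <- function(x, centers = NULL, box = 500, pixelSize = 20,
                         channel = NULL, cell = 1L, smoothSigma = 100,
                         percentile = 0.995, minSeparation = box / 2) {
    img <- if (is(x, "PixelImage")) x
           else renderHistogram(x, pixelSize, channel = channel)
    p <- pixelSize(img)
    m <- pixelData(img)
    hw <- floor(box / (2 * p))
    if (is.null(centers)) {
        sm <- EBImage::imageData(EBImage::gblur(m, max(1, smoothSigma / p)))
        thr <- stats::quantile(sm[sm > 0], percentile, names = FALSE)
        n1 <- nrow(sm); n2 <- ncol(sm)
        isMax <- sm >= thr
        for (di in -1:1) for (dj in -1:1) {
            if (di == 0 && dj == 0) next
            shifted <- matrix(-Inf, n1, n2)
            si <- seq_len(n1) + di; sj <- seq_len(n2) + dj
            oi <- si >= 1 & si <= n1; oj <- sj >= 1 & sj <= n2
            shifted[oi, oj] <- sm[si[oi], sj[oj]]
            isMax <- isMax & (sm >= shifted)
        }
        pk <- which(isMax, arr.ind = TRUE)
        if (!nrow(pk)) {
            return(ClusterStack(list(), pixelSize = p,
                                info = emptyStackInfo()))
        }
        val <- sm[pk]
        pk <- pk[order(-val), , drop = FALSE]
        cs <- cbind(imageOrigin(img)[1] + (pk[, 1] - 0.5) * p,
                    imageOrigin(img)[2] + (pk[, 2] - 0.5) * p)
        keep <- rep(TRUE, nrow(cs))
        for (i in seq_len(nrow(cs))[-1]) {
            prev <- cs[seq_len(i - 1), , drop = FALSE][keep[seq_len(i - 1)], ,
                                                       drop = FALSE]
            if (nrow(prev) &&
                min(sqrt(rowSums(sweep(prev, 2, cs[i, ])^2))) < minSeparation)
                keep[i] <- FALSE
        }
        centers <- cs[keep, , drop = FALSE]
    }
    centers <- as.matrix(centers)
    imgs <- list(); meta <- NULL
    for (k in seq_len(nrow(centers))) {
        ci <- floor((centers[k, 1] - imageOrigin(img)[1]) / p) + 1
        cj <- floor((centers[k, 2] - imageOrigin(img)[2]) / p) + 1
        i0 <- ci - hw; i1 <- ci + hw; j0 <- cj - hw; j1 <- cj + hw
        if (i0 < 1 || j0 < 1 || i1 > nrow(m) || j1 > ncol(m)) {
            warning("cluster ", k, " box exceeds image bounds; skipped")
            next
        }
        imgs[[length(imgs) + 1L]] <- m[i0:i1, j0:j1]
        meta <- rbind(meta, data.frame(cell = cell, cluster = k,
                                       dx = 0, dy = 0, rotation = 0,
                                       normalized = FALSE,
                                       cx = centers[k, 1], cy = centers[k, 2]))
    }
    if (is.null(meta)) meta <- emptyStackInfo()
    ClusterStack(imgs, pixelSize = p, info = meta)
}

emptyStackInfo <- function()
    data.frame(cell = integer(0), cluster = integer(0), dx = numeric(0),
               dy = numeric(0), rotation = numeric(0), normalized = logical(0),
               cx = numeric(0), cy = numeric(0))

#' Normalize cluster images by their pixel standard deviation
#'
#' Each image is divided by the standard deviation of its own pixel values;
#' the mean is deliberately not subtracted. The operation is idempotent after
#' the first application (a unit-std image is returned unchanged).
#'
#' @param stack a \linkS4class{ClusterStack}.
#' @return The normalized stack.
#' @export
normalizeImages <- function(stack) {
    imgs <- lapply(seq_along(stack@images), function(k) {
        s <- stats::sd(stack@images[[k]])
        if (s == 0)
            stop("cluster image ", k, " is flat (zero pixel standard deviation)")
        stack@images[[k]] / s
    })
    info <- stack@info
    info$normalized <- TRUE
    new("ClusterStack", images = imgs, pixelSize = stack@pixelSize, info = info)
}

#' Iteratively align cluster images to their rotationally averaged sum
#'
#' Repeats: (1) sum the stack and rotationally average the sum to form the
#' reference; (2) align each image to the reference by exhaustive rotation
#' search plus subpixel translational cross-correlation; (3) re-transform each
#' image from its pristine original with the accumulated rotation and shift.
#' Iteration stops when the mean transform update falls below 0.1 pixel and
#' 0.5 degrees. Because the reference is rotationally symmetric by
#' construction, the per-image rotations are reported but essentially
#' unconstrained; the alignment is driven by the translations.
#'
#' @param stack a normalized \linkS4class{ClusterStack}.
#' @param nIterations maximum number of iterations (default 5).
#' @param rotStep rotation search step in degrees (default 2); 0 disables the
#'   rotation search (pure translation alignment).
#' @return The aligned stack; \code{stackInfo} records the applied shifts
#'   (px) and rotations (deg).
#' @export
alignToRotationalMean <- function(stack, nIterations = 5, rotStep = 2) {
    n <- length(stack)
    if (!n) stop("empty cluster stack")
    orig <- stack@images
    info <- stack@info
    rot <- info$rotation; dx <- info$dx; dy <- info$dy
    cur <- mapply(function(im, r, sx, sy) transformImage(im, r, sx, sy),
                  orig, rot, dx, dy, SIMPLIFY = FALSE)
    thetas <- if (rotStep > 0) seq(0, 360 - rotStep, by = rotStep) else 0
    for (iter in seq_len(nIterations)) {
        ref <- rotationalAverageImage(Reduce(`+`, cur))
        newRot <- rot; newDx <- dx; newDy <- dy
        for (k in seq_len(n)) {
            best <- NULL
            for (th in thetas) {
                rotated <- transformImage(orig[[k]], th, 0, 0)
                reg <- registerTranslation(ref, rotated, upsample = 1)
                if (is.null(best) || reg$peak > best$peak)
                    best <- list(peak = reg$peak, theta = th)
            }
            rotated <- transformImage(orig[[k]], best$theta, 0, 0)
            reg <- registerTranslation(ref, rotated, upsample = 20)
            newRot[k] <- best$theta
            newDx[k] <- reg$shift[1]; newDy[k] <- reg$shift[2]
        }
        dRot <- abs((newRot - rot + 180) %% 360 - 180)
        dShift <- sqrt((newDx - dx)^2 + (newDy - dy)^2)
        rot <- newRot; dx <- newDx; dy <- newDy
        cur <- mapply(function(im, r, sx, sy) transformImage(im, r, sx, sy),
                      orig, rot, dx, dy, SIMPLIFY = FALSE)
        if (mean(dShift) < 0.1 && mean(dRot) < 0.5) break
    }
    info$rotation <- rot; info$dx <- dx; info$dy <- dy
    new("ClusterStack", images = cur, pixelSize = stack@pixelSize, info = info)
}

## Radial bin index of every pixel relative to the box centre, 1-based,
## bin width in pixels.
pixelRadialBins <- function(n1, n2, binWidthPx) {
    cx <- (n1 + 1) / 2; cy <- (n2 + 1) / 2
    g <- expand.grid(x = seq_len(n1), y = seq_len(n2))
    r <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
    matrix(floor(r / binWidthPx) + 1L, n1, n2)
}

#' Rotational average of a square image
#'
#' Replaces every pixel by the mean over all pixels in the same radial bin
#' (bin width one pixel) about the box centre. Images that are already
#' rotationally symmetric in this binning are fixed points of the operation.
#'
#' @param image square numeric matrix.
#' @return matrix of the same size.
#' @export
rotationalAverageImage <- function(image) {
    bins <- pixelRadialBins(nrow(image), ncol(image), 1)
    prof <- tapply(image, bins, mean)
    matrix(prof[as.character(bins)], nrow(image), ncol(image))
}

#' Radial profile of a square image
#'
#' The profile value at radial bin j is the mean over all pixels whose centre
#' distance from the box centre lies in \code{[(j-1) d, j d)}.
#'
#' @param image square numeric matrix or \linkS4class{PixelImage}.
#' @param pixelSize pixel edge in nm (taken from a PixelImage input).
#' @param binWidth radial bin width in nm (default: one pixel).
#' @param rmax maximum radius in nm (default: half the box edge).
#' @return A \linkS4class{RadialProfile}; for image input the raw ring means
#'   already form a density trace.
#' @export
radialProfileImage <- function(image, pixelSize = 1, binWidth = NULL,
                               rmax = NULL) {
    if (is(image, "PixelImage")) {
        pixelSize <- pixelSize(image)
        image <- pixelData(image)
    }
    if (is.null(binWidth)) binWidth <- pixelSize
    if (is.null(rmax)) rmax <- nrow(image) / 2 * pixelSize
    bins <- pixelRadialBins(nrow(image), ncol(image), binWidth / pixelSize)
    nb <- floor(rmax / binWidth)
    vals <- vapply(seq_len(nb), function(j) {
        sel <- bins == j
        if (any(sel)) mean(image[sel]) else NA_real_
    }, numeric(1))
    vals[is.na(vals)] <- 0
    tot <- sum(vals)
    new("RadialProfile", binWidth = binWidth,
        binCenters = (seq_len(nb) - 0.5) * binWidth,
        raw = vals, density = vals,
        normalized = if (tot > 0) vals / tot else vals,
        perCell = matrix(numeric(0), 0, nb), mean = numeric(0),
        sd = numeric(0))
}

#' Per-cell radial-profile statistics of an aligned stack
#'
#' All aligned particles of each cell are averaged (equivalently: rotationally
#' averaged and summed, then scaled), the radial profile of every cell average
#' is computed, and the pointwise mean and sample standard deviation across
#' cells are reported.
#'
#' @param stack an aligned \linkS4class{ClusterStack} whose \code{info$cell}
#'   groups the particles.
#' @param binWidth radial bin width in nm (default: the pixel size).
#' @param rmax maximum radius in nm (default: half the box edge).
#' @return A \linkS4class{RadialProfile} with the per-cell profile matrix and
#'   cross-cell mean/sd.
#' @export
perCellProfileStats <- function(stack, binWidth = NULL, rmax = NULL) {
    cells <- unique(stack@info$cell)
    if (length(cells) == 1)
        warning("single cell: standard deviation reported as 0")
    if (is.null(binWidth)) binWidth <- stack@pixelSize
    prof <- NULL
    for (ce in cells) {
        idx <- which(stack@info$cell == ce)
        avg <- Reduce(`+`, stack@images[idx]) / length(idx)
        rp <- radialProfileImage(avg, pixelSize = stack@pixelSize,
                                 binWidth = binWidth, rmax = rmax)
        prof <- rbind(prof, profileDensity(rp))
    }
    rownames(prof) <- as.character(cells)
    mu <- colMeans(prof)
    sdv <- if (nrow(prof) > 1) apply(prof, 2, stats::sd) else rep(0, ncol(prof))
    tot <- sum(mu)
    new("RadialProfile", binWidth = binWidth,
        binCenters = (seq_len(ncol(prof)) - 0.5) * binWidth,
        raw = mu, density = mu,
        normalized = if (tot > 0) mu / tot else mu,
        perCell = prof, mean = mu, sd = sdv)
}

#' Half-radius of a radial profile
#'
#' The radius at which the cumulative radial profile reaches 50 percent of its
#' total, linearly interpolated within the crossing bin. For a disk of
#' constant density and sharp edges this is exactly half the disk radius, and
#' less than half for particles whose density decreases at the periphery.
#'
#' @param profile a \linkS4class{RadialProfile}.
#' @return radius in nm.
#' @export
halfRadius <- function(profile) {
    v <- profileDensity(profile)
    tot <- sum(v)
    if (tot <= 0) stop("profile has zero total mass")
    cum <- cumsum(v) / tot
    j <- which(cum >= 0.5)[1]
    left <- (j - 1) * profile@binWidth
    prev <- if (j == 1) 0 else cum[j - 1]
    left + (0.5 - prev) / (cum[j] - prev) * profile@binWidth
}

#' Center of mass of a cluster (Eq. of the localization analysis)
#'
#' The mean of all localizations of the given channel within
#' \code{searchRadius} of the initial position.
#'
#' @param table a corrected \linkS4class{LocalizationTable}.
#' @param center initial position, nm (length 2).
#' @param searchRadius gate radius in nm (default 250).
#' @param channel channel used for the centre (default 1).
#' @return list with \code{M} (the centre of mass) and \code{N} (number of
#'   contributing localizations); \code{NULL} when no localization falls
#'   within the gate.
#' @keywords internal
clusterCenterOfMass <- function(table, center, searchRadius = 250,
                                channel = 1L) {
    d <- locData(table)
    d <- d[d$channel == channel, , drop = FALSE]
    r <- sqrt((d$x - center[1])^2 + (d$y - center[2])^2)
    sel <- r <= searchRadius
    if (!any(sel)) return(NULL)
    list(M = c(mean(d$x[sel]), mean(d$y[sel])), N = sum(sel))
}

#' Ring surface area of radial histogram bins
#'
#' @param j bin index (1-based).
#' @param d bin width in nm.
#' @return the ring area \code{pi (2j - 1) d^2} in nm^2.
#' @export
ringArea <- function(j, d) pi * (2 * j - 1) * d^2

#' Center-of-mass radial profiles from localization data
#'
#' The full localization-based profile analysis: for every cluster the exact
#' centre is the centre of mass of the centre-channel localizations within
#' \code{searchRadius} (250 nm) of the initial position; the distance from
#' that centre to every localization of the profiled channel is histogrammed
#' from 0 to \code{rmax} in bins of width \code{binWidth}; counts are divided
#' by the ring surface areas \code{S_j = pi (2j - 1) d^2} and normalized so
#' their sum equals unity (or scaled by a supplied normalization coefficient,
#' to compare conditions on a common scale); profiles are averaged over the
#' clusters of each cell, and the mean and sample standard deviation across
#' cells are reported.
#'
#' @param table a corrected \linkS4class{LocalizationTable} (drift and
#'   chromatic corrected, consecutive localizations merged beforehand).
#' @param centers n x 2 matrix of initial cluster positions, nm.
#' @param cell cell id per cluster (default: all one cell).
#' @param searchRadius centre-of-mass gate, nm (default 250).
#' @param rmax histogram range, nm (default 200).
#' @param binWidth histogram bin width d, nm (default 20).
#' @param centerChannel channel defining the cluster centres (e.g. CENP-A).
#' @param profileChannel channel whose localizations are profiled (defaults
#'   to \code{centerChannel}; set to the second channel for e.g. HJURP).
#' @param normCoefficient optional externally stored normalization
#'   coefficient replacing each cluster's own (sum of area-corrected counts).
#' @return A \linkS4class{RadialProfile} with per-cell rows and cross-cell
#'   mean/sd; attributes \code{centers} (data.frame with the refined centres
#'   M and their N) and \code{normCoefficients} (per cluster).
#' @export
comRadialProfile <- function(table, centers, cell = NULL, searchRadius = 250,
                             rmax = 200, binWidth = 20, centerChannel = 1L,
                             profileChannel = centerChannel,
                             normCoefficient = NULL) {
    centers <- as.matrix(centers)
    nC <- nrow(centers)
    if (is.null(cell)) cell <- rep(1L, nC)
    d <- locData(table)
    pd <- d[d$channel == profileChannel, , drop = FALSE]
    nb <- round(rmax / binWidth)
    S <- ringArea(seq_len(nb), binWidth)
    profs <- matrix(NA_real_, nC, nb)
    coefs <- numeric(nC)
    meta <- NULL
    for (k in seq_len(nC)) {
        cm <- clusterCenterOfMass(table, centers[k, ], searchRadius,
                                  centerChannel)
        if (is.null(cm)) {
            warning("cluster ", k, ": no localization within the search ",
                    "radius; skipped")
            next
        }
        r <- sqrt((pd$x - cm$M[1])^2 + (pd$y - cm$M[2])^2)
        j <- floor(r / binWidth) + 1L
        counts <- tabulate(j[j <= nb], nbins = nb)
        corrected <- counts / S
        coefs[k] <- sum(corrected)
        if (coefs[k] == 0) {
            warning("cluster ", k, ": no localization within the histogram ",
                    "range; skipped")
            next
        }
        norm <- if (is.null(normCoefficient)) coefs[k] else normCoefficient
        profs[k, ] <- corrected / norm
        meta <- rbind(meta, data.frame(cluster = k, cell = cell[k],
                                       Mx = cm$M[1], My = cm$M[2], N = cm$N))
    }
    ok <- !is.na(profs[, 1])
    if (!any(ok)) stop("no usable cluster")
    cells <- unique(cell[ok])
    perCell <- do.call(rbind, lapply(cells, function(ce) {
        colMeans(profs[ok & cell == ce, , drop = FALSE])
    }))
    rownames(perCell) <- as.character(cells)
    mu <- colMeans(perCell)
    sdv <- if (nrow(perCell) > 1) apply(perCell, 2, stats::sd)
           else rep(0, ncol(perCell))
    out <- new("RadialProfile", binWidth = binWidth,
               binCenters = (seq_len(nb) - 0.5) * binWidth,
               raw = mu, density = mu, normalized = mu,
               perCell = perCell, mean = mu, sd = sdv)
    attr(out, "centers") <- meta
    attr(out, "normCoefficients") <- coefs
    out
}
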