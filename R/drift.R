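#' @include AllClasses.R accessors.R localization-io.R utils-geometry.R
NULL

#' Apply or subtract a drift trajectory
#'
#' \code{applyDrift} adds the per-frame shift to the coordinates (used by the
#' simulator); \code{correctDrift} subtracts it, leaving all other fields
#' unchanged. The two are exact inverses.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param trajectory a \linkS4class{DriftTrajectory} covering every frame of
#'   the table.
#' @return A corrected \linkS4class{LocalizationTable}.
#' @export
correctDrift <- function(table, trajectory) {
    shiftDrift(table, trajectory, -1)
}

#' @rdname correctDrift
#' @export
applyDrift <- function(table, trajectory) {
    shiftDrift(table, trajectory, +1)
}

shiftDrift <- function(table, trajectory, sign) {
    d <- locData(table)
    sh <- driftShifts(trajectory)
    if (nrow(d) && max(d$frame) > nrow(sh))
        stop("frame ", max(d$frame), " outside the trajectory domain (",
             nrow(sh), " frames)")
    d$x <- d$x + sign * sh[d$frame, 1]
    d$y <- d$y + sign * sh[d$frame, 2]
    if (ncol(sh) == 3) {
        if (all(is.na(d$z)))
            stop("3D trajectory applied to a 2D localization table")
        d$z <- d$z + sign * sh[d$frame, 3]
    }
    new("LocalizationTable", data = d)
}

#' Estimate sample drift by subset cross-correlation
#'
#' The acquisition is divided into consecutive frame subsets; a histogram
#' image (default pixelation 20 nm) is rendered from each subset and the shift
#' of every subset relative to the first is detected with subpixel precision
#' by Fourier-upsampled cross-correlation. Lateral drift comes from the XY
#' projection; for 3D tables the axial drift is the average of the shifts
#' found in the XZ and YZ projections. Anchor shifts are interpolated linearly
#' over the intermediate frames and the whole procedure is repeated on the
#' corrected table until the update falls below 1 nm, assuring absence of
#' detectable residual drift.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param nSubsets number of consecutive subsets (default 10).
#' @param pixelSize histogram pixelation in nm (default 20).
#' @param nIterations maximum refinement passes (default 3).
#' @param upsample cross-correlation upsampling factor (default 20, i.e. 1 nm
#'   granularity at 20 nm pixels).
#' @param blurSigma Gaussian smoothing (in pixels) applied to the subset
#'   histograms before correlation; tempers the speckle of sparse
#'   single-molecule histograms so the broad correlation peak is localized
#'   reliably (default 2).
#' @return A \linkS4class{DriftTrajectory} (one row per frame, zero at the
#'   first-subset anchor) with an \code{iterationRMS} attribute giving the
#'   RMS anchor-shift magnitude estimated in each pass.
#' @export
estimateDrift <- function(table, nSubsets = 10, pixelSize = 20,
                          nIterations = 3, upsample = 20, blurSigma = 2) {
    stopifnot(nSubsets >= 2)
    d <- locData(table)
    if (!nrow(d)) stop("empty localization table")
    maxFrame <- max(d$frame)
    dims <- locDims(table)
    breaks <- round(seq(0, maxFrame, length.out = nSubsets + 1))
    subset <- findInterval(d$frame, breaks[-1] + 0.5) + 1L
    anchors <- (breaks[-1] + breaks[-(nSubsets + 1)] + 1) / 2
    bounds <- function(u, p) c(floor(min(u) / p) * p,
                               (floor(max(u) / p) + 1) * p)
    bx <- bounds(d$x, pixelSize); by <- bounds(d$y, pixelSize)
    bz <- if (dims == 3) bounds(d$z, pixelSize) else NULL
    total <- matrix(0, maxFrame, dims)
    work <- table
    rmsLog <- numeric(0)
    for (iter in seq_len(nIterations)) {
        w <- locData(work)
        shifts <- matrix(NA_real_, nSubsets, dims)
        imgs1 <- NULL
        for (s in seq_len(nSubsets)) {
            rows <- which(subset == s)
            if (length(rows) < 10) {
                warning("drift subset ", s, " has fewer than 10 localizations; ",
                        "anchor skipped")
                next
            }
            ws <- work[rows]
            render <- function(axes, b1, b2) {
                m <- pixelData(renderHistogram(ws, pixelSize,
                                               bounds = c(b1, b2), axes = axes))
                if (blurSigma > 0) EBImage::imageData(EBImage::gblur(m, blurSigma))
                else m
            }
            ixy <- render(c(1, 2), bx, by)
            if (stats::sd(ixy) == 0)
                stop("degenerate flat histogram in drift subset ", s)
            if (s == 1) {
                imgs1 <- list(xy = ixy)
                if (dims == 3) {
                    imgs1$xz <- render(c(1, 3), bx, bz)
                    imgs1$yz <- render(c(2, 3), by, bz)
                }
                shifts[1, ] <- 0
                next
            }
            # data drifted by +d moves the image content by +d: the
            # registration shift of subset s against subset 1 is -d
            sxy <- registerTranslation(imgs1$xy, ixy, upsample)$shift
            est <- -sxy * pixelSize
            if (dims == 3) {
                sxz <- registerTranslation(imgs1$xz, render(c(1, 3), bx, bz),
                                           upsample)$shift
                syz <- registerTranslation(imgs1$yz, render(c(2, 3), by, bz),
                                           upsample)$shift
                est <- c(est, -(sxz[2] + syz[2]) / 2 * pixelSize)
            }
            shifts[s, ] <- est
        }
        ok <- which(!is.na(shifts[, 1]))
        if (length(ok) < 2) stop("not enough usable drift subsets")
        upd <- vapply(seq_len(dims), function(ax) {
            stats::approx(anchors[ok], shifts[ok, ax], xout = seq_len(maxFrame),
                          rule = 2)$y
        }, numeric(maxFrame))
        rmsLog <- c(rmsLog, sqrt(mean(shifts[ok, , drop = FALSE]^2)))
        total <- total + upd
        work <- correctDrift(table, DriftTrajectory(total))
        if (max(abs(shifts[ok, ]))< 1) break
    }
    traj <- DriftTrajectory(total)
    attr(traj, "iterationRMS") <- rmsLog
    traj
}

#' Build a linear drift trajectory
#'
#' @param nFrames number of frames.
#' @param totalShift total drift over the acquisition, nm (length 2 or 3);
#'   frame 1 has zero shift.
#' @return A \linkS4class{DriftTrajectory}.
#' @export
linearDrift <- function(nFrames, totalShift) {
    f <- (seq_len(nFrames) - 1) / max(1, nFrames - 1)
    DriftTrajectory(outer(f, totalShift))
}
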