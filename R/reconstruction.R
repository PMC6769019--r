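#' @include AllClasses.R accessors.R utils-geometry.R simulate.R
NULL

## ZYZ Euler rotation matrix (degrees): camera = R %*% volume.
## Image coordinates are rows 1-2 of R; the viewing axis is row 3.
eulerMatrixZYZ <- function(alpha, beta, gamma) {
    a <- alpha * pi / 180; b <- beta * pi / 180; g <- gamma * pi / 180
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
    Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
    Rz(a) %*% Ry(b) %*% Rz(g)
}

## Viewing axis (third row of R); depends on beta and gamma only.
viewAxisZYZ <- function(beta, gamma) {
    b <- beta * pi / 180; g <- gamma * pi / 180
    cbind(-sin(b) * cos(g), sin(b) * sin(g), cos(b))
}

## Parallel-beam projection of a cubic volume along the viewing axis of one
## ZYZ orientation; output pixel grid matches the volume grid.
projectVolumeImage <- function(volume, ang) {
    v <- voxelData(volume)
    N <- dim(v)[1]
    R <- eulerMatrixZYZ(ang[1], ang[2], ang[3])
    c0 <- (N + 1) / 2
    g <- as.matrix(expand.grid(u = seq_len(N) - c0, v = seq_len(N) - c0,
                               w = seq_len(N) - c0))
    volc <- g %*% R           # row vectors: vol = t(R) %*% cam
    s <- trilinearSample(v, volc[, 1] + c0, volc[, 2] + c0, volc[, 3] + c0)
    matrix(rowSums(matrix(s, N * N, N)), N, N)
}

#' Compute the sinogram (Radon transform) of a square image
#'
#' Line projections by rotate-and-sum with bilinear interpolation over
#' in-plane angles \code{[0, 180)}. The image is first embedded in a larger
#' canvas so that rotation clips nothing; every line then conserves the
#' image's total mass.
#'
#' @param image square numeric matrix or \linkS4class{PixelImage}.
#' @param angularStep angular step in degrees (default 1); must divide 180.
#' @return A \linkS4class{Sinogram}.
#' @export
computeSinogram <- function(image, angularStep = 1) {
    if (is(image, "PixelImage")) image <- pixelData(image)
    if (nrow(image) != ncol(image)) stop("sinogram input must be square")
    if (180 %% angularStep != 0) stop("angularStep must divide 180")
    N <- nrow(image)
    pad <- ceiling(N * (sqrt(2) - 1) / 2) + 2
    L <- N + 2 * pad
    canvas <- matrix(0, L, L)
    canvas[pad + seq_len(N), pad + seq_len(N)] <- image
    angles <- seq(0, 180 - angularStep, by = angularStep)
    lines <- t(vapply(angles, function(th) {
        rowSums(rotateImage(canvas, -th))
    }, numeric(L)))
    new("Sinogram", lines = lines, angularStep = angularStep, angles = angles)
}

## Band-pass filter, mean-subtract and L2-normalize every sinogram line,
## then extend to 360 degrees (the line at theta + 180 is the reversed line
## at theta) so that common-line directions keep their sign. The ramp part
## of the filter suppresses the low-frequency envelope shared by all
## directions (which would make every pair of lines correlate near 1); the
## Gaussian rolloff keeps amplified high-frequency noise in check.
normalizedSinogram360 <- function(sg, lineFilter = TRUE) {
    m <- sinogramLines(sg)
    if (lineFilter) {
        L <- ncol(m)
        k <- abs(fftIndex(L))
        H <- k * exp(-(k / (0.1 * L))^2)
        m <- t(apply(m, 1, function(r)
            Re(stats::fft(stats::fft(r) * H, inverse = TRUE)) / L))
    }
    m <- m - rowMeans(m)
    nrm <- sqrt(rowSums(m^2))
    nrm[nrm == 0] <- 1
    m <- m / nrm
    rbind(m, m[, rev(seq_len(ncol(m))), drop = FALSE])
}

## Bilinear lookup with angular wraparound in a 360-degree correlation map.
corrLookup <- function(C, ti, tj, step) {
    n <- nrow(C)
    i <- (ti / step) %% n; j <- (tj / step) %% n
    i0 <- floor(i); j0 <- floor(j)
    fi <- i - i0; fj <- j - j0
    i1 <- (i0 + 1) %% n; j1 <- (j0 + 1) %% n
    C[cbind(i0 + 1, j0 + 1)] * (1 - fi) * (1 - fj) +
        C[cbind(i1 + 1, j0 + 1)] * fi * (1 - fj) +
        C[cbind(i0 + 1, j1 + 1)] * (1 - fi) * fj +
        C[cbind(i1 + 1, j1 + 1)] * fi * fj
}

## Predicted common-line angles (degrees, mod 360) between orientations.
## Returns NA when the viewing axes are (anti)parallel.
commonLineAngles <- function(Ri, Rj) {
    d <- c(Ri[3, 2] * Rj[3, 3] - Ri[3, 3] * Rj[3, 2],
           Ri[3, 3] * Rj[3, 1] - Ri[3, 1] * Rj[3, 3],
           Ri[3, 1] * Rj[3, 2] - Ri[3, 2] * Rj[3, 1])
    nd <- sqrt(sum(d^2))
    if (nd < 1e-9) return(c(NA_real_, NA_real_))
    d <- d / nd
    ci <- Ri[1:2, ] %*% d
    cj <- Rj[1:2, ] %*% d
    (c(atan2(ci[2], ci[1]), atan2(cj[2], cj[1])) * 180 / pi) %% 360
}

#' Assign Euler angles to a stack of projections by common lines
#'
#' Angular reconstitution: any two 2D projections of the same 3D object share
#' a 1D line projection, found as the best-correlating pair of lines in their
#' sinograms. Image 1 is fixed at the identity orientation (gauge); every
#' further image is assigned by a coarse orientation grid search that scores
#' candidate orientations by the sinogram correlation at the predicted
#' common-line angles against the already-assigned anchor images, followed by
#' continuous refinement maximizing the mean common-line correlation. The
#' global rotation and the handedness (mirror) of the assignment are
#' fundamentally unresolvable and flagged as such.
#'
#' @param stack a \linkS4class{ClusterStack} with at least 3 images.
#' @param angularStep sinogram angular step, degrees (default 1).
#' @param gridStep coarse orientation grid step, degrees (default 10).
#' @param maxAnchors number of anchor images used when scoring (default 12).
#' @param refinePasses additional refinement sweeps over all images after the
#'   sequential assignment (default 2).
#' @param smoothSigma Gaussian smoothing (pixels) applied to the images
#'   before the sinograms are computed; tempers pixel noise (default 1, 0
#'   disables).
#' @return An \linkS4class{EulerAngleSet} (ZYZ, degrees) with
#'   \code{mirrorAmbiguous = TRUE} and attribute \code{meanCorrelation}, the
#'   mean common-line correlation of the final assignment.
#' @export
assignAngles <- function(stack, angularStep = 1, gridStep = 10,
                         maxAnchors = 12, refinePasses = 2, smoothSigma = 1) {
    n <- length(stack)
    if (n < 3) stop("need at least 3 images for angular reconstitution")
    imgs <- stackImages(stack)
    if (smoothSigma > 0)
        imgs <- lapply(imgs, function(m)
            EBImage::imageData(EBImage::gblur(m, smoothSigma)))
    sgs <- lapply(imgs, computeSinogram, angularStep = angularStep)
    S <- lapply(sgs, normalizedSinogram360)
    # rotationally symmetric images have near-identical lines at all angles:
    # no unique common line exists and the assignment is degenerate
    selfCorr <- vapply(S, function(m) {
        stats::median(as.vector(m %*% m[1, ]))
    }, numeric(1))
    if (stats::median(selfCorr) > 0.98)
        stop("sinogram lines are nearly identical across angles ",
             "(rotationally symmetric images): angular assignment is ",
             "degenerate")
    getC <- function(i, j) S[[i]] %*% t(S[[j]])
    angles <- matrix(0, n, 3)
    score <- function(ang, anchors, Cs) {
        Rk <- eulerMatrixZYZ(ang[1], ang[2], ang[3])
        tot <- 0; m <- 0
        for (ai in seq_along(anchors)) {
            a <- anchors[ai]
            Ra <- eulerMatrixZYZ(angles[a, 1], angles[a, 2], angles[a, 3])
            th <- commonLineAngles(Ra, Rk)
            if (is.na(th[1])) next
            tot <- tot + corrLookup(Cs[[ai]], th[1], th[2], angularStep)
            m <- m + 1
        }
        if (m == 0) -1 else tot / m
    }
    pickAnchors <- function(pool, k) {
        pool <- setdiff(pool, k)
        if (length(pool) > maxAnchors)
            pool[round(seq(1, length(pool), length.out = maxAnchors))]
        else pool
    }
    anchorCs <- function(anchors, k) lapply(anchors, getC, j = k)
    gridSearch <- function(k, anchors, Cs) {
        alphas <- seq(0, 360 - gridStep, by = gridStep)
        best <- c(-Inf, 0, 0, 0)
        Ranch <- lapply(anchors, function(a)
            eulerMatrixZYZ(angles[a, 1], angles[a, 2], angles[a, 3]))
        for (b in seq(0, 180, by = gridStep)) {
            for (g in seq(0, 360 - gridStep, by = gridStep)) {
                R0 <- eulerMatrixZYZ(0, b, g)
                vals <- numeric(length(alphas)); m <- 0
                for (ai in seq_along(anchors)) {
                    th <- commonLineAngles(Ranch[[ai]], R0)
                    if (is.na(th[1])) next
                    # alpha only rotates the candidate's in-plane line angle
                    vals <- vals + corrLookup(Cs[[ai]],
                                              rep(th[1], length(alphas)),
                                              th[2] + alphas, angularStep)
                    m <- m + 1
                }
                if (m == 0) next
                vals <- vals / m
                iBest <- which.max(vals)
                if (vals[iBest] > best[1])
                    best <- c(vals[iBest], alphas[iBest], b, g)
            }
        }
        best[2:4]
    }
    refine2 <- function(start, anchors, Cs) {
        res <- stats::optim(start, function(p) -score(p, anchors, Cs),
                            method = "Nelder-Mead",
                            control = list(maxit = 200, reltol = 1e-6))
        res$par
    }
    ## Triplet bootstrap: a pair of projections alone leaves one relative
    ## degree of freedom undetermined, so images 2 and 3 are placed jointly.
    ## With image 1 at the identity, the common line with image 1 fixes each
    ## of R2, R3 up to the dihedral angle of its projection plane about that
    ## line; the 2-3 common-line correlation scores the (phi2, phi3) grid.
    matrixToZYZ <- function(R) {
        b <- acos(pmin(1, pmax(-1, R[3, 3])))
        if (sin(b) > 1e-9) {
            a <- atan2(R[2, 3], R[1, 3])
            g <- atan2(R[3, 2], -R[3, 1])
        } else {
            a <- atan2(R[2, 1], R[1, 1])
            g <- 0
        }
        c(a, b, g) * 180 / pi
    }
    dihedralOrientation <- function(theta1, theta2, phi) {
        t1 <- theta1 * pi / 180; ph <- phi * pi / 180
        u <- c(cos(t1), sin(t1), 0)
        # rotate e3 about u by phi (Rodrigues)
        e3 <- c(0, 0, 1)
        z2 <- e3 * cos(ph) + c(u[2] * e3[3] - u[3] * e3[2],
                               u[3] * e3[1] - u[1] * e3[3],
                               u[1] * e3[2] - u[2] * e3[1]) * sin(ph) +
              u * sum(u * e3) * (1 - cos(ph))
        w <- c(z2[2] * u[3] - z2[3] * u[2], z2[3] * u[1] - z2[1] * u[3],
               z2[1] * u[2] - z2[2] * u[1])
        Rp <- rbind(u, w, z2)
        t2 <- theta2 * pi / 180
        Rz2 <- matrix(c(cos(t2), sin(t2), 0, -sin(t2), cos(t2), 0, 0, 0, 1),
                      3, 3)
        Rz2 %*% Rp
    }
    peakAngles <- function(C) {
        pk <- arrayInd(which.max(C), dim(C))
        (pk - 1) * angularStep
    }
    bootstrapTriplet <- function(i1, i2, i3) {
        th12 <- peakAngles(getC(i1, i2))
        th13 <- peakAngles(getC(i1, i3))
        C23 <- getC(i2, i3)
        phiGrid <- seq(0, 360 - 3, by = 3)
        best <- c(-Inf, 0, 0)
        for (p2 in phiGrid) {
            R2 <- dihedralOrientation(th12[1], th12[2], p2)
            v <- vapply(phiGrid, function(p3) {
                R3 <- dihedralOrientation(th13[1], th13[2], p3)
                th <- commonLineAngles(R2, R3)
                if (is.na(th[1])) return(-1)
                corrLookup(C23, th[1], th[2], angularStep)
            }, numeric(1))
            i <- which.max(v)
            if (v[i] > best[1]) best <- c(v[i], p2, phiGrid[i])
        }
        list(score = best[1],
             a2 = matrixToZYZ(dihedralOrientation(th12[1], th12[2], best[2])),
             a3 = matrixToZYZ(dihedralOrientation(th13[1], th13[2], best[3])))
    }
    # try a few seed triplets and keep the most self-consistent one: a single
    # unlucky pair (near-parallel views, weak common line) would otherwise
    # poison the entire sequential assignment
    pool <- seq_len(min(n, 5))
    cands <- utils::combn(pool, 3)
    bestTrip <- NULL
    for (ci in seq_len(min(ncol(cands), 6))) {
        tr <- cands[, ci]
        bs <- bootstrapTriplet(tr[1], tr[2], tr[3])
        # consistency check: refine the two placed images within the triplet
        # and re-measure the mean common-line correlation of all three pairs
        angles[tr[1], ] <- c(0, 0, 0)
        angles[tr[2], ] <- bs$a2
        angles[tr[3], ] <- bs$a3
        a2 <- refine2(bs$a2, c(tr[1], tr[3]), anchorCs(c(tr[1], tr[3]), tr[2]))
        angles[tr[2], ] <- a2
        a3 <- refine2(bs$a3, c(tr[1], tr[2]), anchorCs(c(tr[1], tr[2]), tr[3]))
        angles[tr[3], ] <- a3
        sc <- (score(a2, c(tr[1], tr[3]), anchorCs(c(tr[1], tr[3]), tr[2])) +
               score(a3, c(tr[1], tr[2]), anchorCs(c(tr[1], tr[2]), tr[3]))) / 2
        if (is.null(bestTrip) || sc > bestTrip$score)
            bestTrip <- list(score = sc, idx = tr, a2 = a2, a3 = a3)
    }
    trip <- bestTrip$idx
    angles[trip[1], ] <- c(0, 0, 0)
    angles[trip[2], ] <- bestTrip$a2
    angles[trip[3], ] <- bestTrip$a3
    assigned <- trip
    for (k in setdiff(seq_len(n), trip)) {
        anchors <- pickAnchors(assigned, k)
        Cs <- anchorCs(anchors, k)
        angles[k, ] <- gridSearch(k, anchors, Cs)
        angles[k, ] <- refine2(angles[k, ], anchors, Cs)
        assigned <- c(assigned, k)
    }
    # coordinate-descent passes with global (re-gridded) per-image moves:
    # escape the local optima a purely sequential assignment can leave behind
    for (pass in seq_len(refinePasses)) {
        for (k in 2:n) {
            anchors <- pickAnchors(seq_len(n), k)
            Cs <- anchorCs(anchors, k)
            cand <- gridSearch(k, anchors, Cs)
            cand <- refine2(cand, anchors, Cs)
            if (score(cand, anchors, Cs) > score(angles[k, ], anchors, Cs))
                angles[k, ] <- cand
            angles[k, ] <- refine2(angles[k, ], anchors, Cs)
        }
    }
    finalScore <- mean(vapply(2:n, function(k) {
        anchors <- pickAnchors(seq_len(n), k)
        score(angles[k, ], anchors, anchorCs(anchors, k))
    }, numeric(1)))
    out <- EulerAngleSet(angles %% 360, mirrorAmbiguous = TRUE)
    attr(out, "meanCorrelation") <- finalScore
    out
}

#' 3D reconstruction by weighted, filtered back-projection
#'
#' Each image is filtered in Fourier space with the ramp filter |q| (the
#' exact-filter compensation for the 1/|q| sampling density of projection
#' planes) and optionally weighted by the inverse local density of viewing
#' orientations, then smeared through the volume along its viewing axis.
#'
#' @param stack a \linkS4class{ClusterStack} of projections.
#' @param angles the corresponding \linkS4class{EulerAngleSet}.
#' @param rampFilter apply the ramp filter (default TRUE).
#' @param orientationWeights apply inverse orientation-density weights
#'   (default TRUE).
#' @param kernelSigma angular width (degrees) of the orientation-density
#'   kernel (default 15).
#' @param normalize scale the output to unit maximum (default TRUE).
#' @return A \linkS4class{Volume3D} normalized to unit maximum. A warning is
#'   emitted when the viewing directions cover the orientation sphere poorly.
#' @export
backprojectVolume <- function(stack, angles, rampFilter = TRUE,
                              orientationWeights = TRUE, kernelSigma = 15,
                              normalize = TRUE) {
    n <- length(stack)
    ang <- eulerAngles(angles)
    if (n != nrow(ang)) stop("stack and angle set sizes differ")
    N <- boxSizePx(stack)
    z <- viewAxisZYZ(ang[, 2], ang[, 3])
    # undirected axis separation; measure coverage and local density
    cosSep <- abs(z %*% t(z))
    sep <- acos(pmin(cosSep, 1)) * 180 / pi
    if (n > 1 && mean(sep[upper.tri(sep)] > 30) < 0.3)
        warning("viewing directions cover the orientation sphere poorly; ",
                "expect an anisotropic reconstruction")
    w <- rep(1, n)
    if (orientationWeights && n > 1) {
        dens <- rowSums(exp(-(sep / kernelSigma)^2))
        w <- 1 / dens
        w <- w / mean(w)
    }
    k <- fftIndex(N) / N
    q <- sqrt(outer(k^2, k^2, "+"))
    imgs <- lapply(seq_len(n), function(i) {
        m <- stackImages(stack)[[i]]
        if (rampFilter) m <- Re(stats::fft(stats::fft(m) * q, inverse = TRUE)) / length(m)
        m * w[i]
    })
    c0 <- (N + 1) / 2
    g <- as.matrix(expand.grid(x = seq_len(N) - c0, y = seq_len(N) - c0,
                               z = seq_len(N) - c0))
    vol <- numeric(N^3)
    for (i in seq_len(n)) {
        R <- eulerMatrixZYZ(ang[i, 1], ang[i, 2], ang[i, 3])
        cam <- g %*% t(R)
        vol <- vol + bilinearSample(imgs[[i]], cam[, 1] + c0, cam[, 2] + c0)
    }
    vol <- array(vol, c(N, N, N))
    if (normalize && max(vol) > 0) vol <- vol / max(vol)
    Volume3D(vol, voxelSize = stack@pixelSize)
}

#' Validate a reconstruction by re-projection
#'
#' Projects the reconstructed volume at the assigned Euler angles and
#' correlates each re-projection with the corresponding input image.
#'
#' @param volume the reconstructed \linkS4class{Volume3D}.
#' @param angles the \linkS4class{EulerAngleSet} used for reconstruction.
#' @param stack the input \linkS4class{ClusterStack}.
#' @return list with \code{perImage} (data.frame image, correlation),
#'   \code{median} correlation, and \code{viewAxes} (the per-image viewing
#'   directions, for Euler-angle coverage plots).
#' @export
reprojectAndValidate <- function(volume, angles, stack) {
    ang <- eulerAngles(angles)
    cors <- vapply(seq_len(nrow(ang)), function(i) {
        rp <- projectVolumeImage(volume, ang[i, ])
        safeCor(rp, stackImages(stack)[[i]])
    }, numeric(1))
    list(perImage = data.frame(image = seq_along(cors), correlation = cors),
         median = stats::median(cors),
         viewAxes = viewAxisZYZ(ang[, 2], ang[, 3]))
}

#' Compare two Euler-angle sets up to global rotation and mirror
#'
#' Aligns the estimated orientations to the reference by the best global
#' rotation (orthogonal Procrustes), separately for every mirror conjugation,
#' and reports the per-image residual rotation angles of the best variant.
#'
#' @param estimated,reference \linkS4class{EulerAngleSet}s of equal length.
#' @return numeric vector of per-image angular errors in degrees.
#' @export
compareAngleSets <- function(estimated, reference) {
    ae <- eulerAngles(estimated); ar <- eulerAngles(reference)
    stopifnot(nrow(ae) == nrow(ar))
    Re_ <- lapply(seq_len(nrow(ae)), function(i)
        eulerMatrixZYZ(ae[i, 1], ae[i, 2], ae[i, 3]))
    mirrors <- list(diag(3), diag(c(1, 1, -1)), diag(c(1, -1, 1)),
                    diag(c(-1, 1, 1)))
    best <- NULL
    for (J in mirrors) {
        Rr <- lapply(seq_len(nrow(ar)), function(i)
            J %*% eulerMatrixZYZ(ar[i, 1], ar[i, 2], ar[i, 3]) %*% J)
        M <- Reduce(`+`, mapply(function(a, b) t(b) %*% a, Re_, Rr,
                                SIMPLIFY = FALSE))
        sv <- svd(M)
        G <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
        err <- vapply(seq_along(Re_), function(i) {
            D <- Re_[[i]] %*% t(Rr[[i]] %*% G)
            ct <- (sum(diag(D)) - 1) / 2
            acos(pmin(1, pmax(-1, ct))) * 180 / pi
        }, numeric(1))
        if (is.null(best) || stats::median(err) < stats::median(best)) best <- err
    }
    best
}
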