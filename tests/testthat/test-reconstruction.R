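test_that("sinograms conserve mass and respect rotational symmetry", {
    n <- 31
    g <- expand.grid(x = 1:n, y = 1:n)
    r <- sqrt((g$x - 16)^2 + (g$y - 16)^2)
    disk <- matrix(as.numeric(r <= 10), n, n)
    sg <- computeSinogram(disk, angularStep = 5)
    lines <- sinogramLines(sg)
    sums <- rowSums(lines)
    expect_true(all(abs(sums - sum(disk)) < 0.005 * sum(disk)))
    # smooth rotationally symmetric image: all lines identical up to the
    # interpolation tolerance
    ball <- matrix(exp(-r^2 / 40), n, n)
    lb <- sinogramLines(computeSinogram(ball, angularStep = 5))
    spread <- apply(lb, 2, function(col) diff(range(col)))
    expect_lt(max(spread), 0.02 * max(lb))
    expect_error(computeSinogram(matrix(0, 4, 5)), "square")
    expect_error(computeSinogram(disk, angularStep = 7), "divide")
})

test_that("a single off-center point traces a sinusoid across the sinogram", {
    n <- 41
    img <- matrix(0, n, n)
    img[29, 21] <- 1                        # offset (8, 0) from center
    sg <- computeSinogram(img, angularStep = 15)
    lines <- sinogramLines(sg)
    L <- ncol(lines)
    c0 <- (L + 1) / 2
    for (i in seq_along(sg@angles)) {
        th <- sg@angles[i] * pi / 180
        peak <- which.max(lines[i, ])
        expected <- c0 + 8 * cos(th)
        expect_lt(abs(peak - expected), 2)
    }
})

test_that("identical images correlate maximally along matching lines", {
    vol <- phantomVolume("asymmetric", n = 32, voxelSize = 10)
    img <- CentroSMLM:::projectVolumeImage(vol, c(30, 70, 10))
    S <- CentroSMLM:::normalizedSinogram360(computeSinogram(img, 2))
    C <- S %*% t(S)
    # the maximum of every row sits on the diagonal (same line)
    expect_true(all(abs(C[cbind(1:45, max.col(C[1:45, ]))] -
                        diag(C)[1:45]) < 1e-9))
})

test_that("relative Euler angles of phantom projections are recovered", {
    vol <- phantomVolume("asymmetric", n = 36, voxelSize = 9)
    truth <- randomEulerAngles(14, seed = 71)
    stack <- projectPhantom(vol, truth)
    est <- assignAngles(stack, angularStep = 2, gridStep = 12,
                        maxAnchors = 13, refinePasses = 2)
    err <- compareAngleSets(est, truth)
    expect_lt(median(err), 5)
    expect_true(est@mirrorAmbiguous)
})

test_that("angle recovery tolerates moderate pixel noise", {
    vol <- phantomVolume("asymmetric", n = 36, voxelSize = 9)
    truth <- randomEulerAngles(14, seed = 73)
    stack <- projectPhantom(vol, truth)
    noisy <- withr::with_seed(74, lapply(stackImages(stack), function(m)
        m + rnorm(length(m), sd = 0.1 * max(m))))
    nstack <- ClusterStack(noisy, pixelSize = stack@pixelSize)
    est <- assignAngles(nstack, angularStep = 2, gridStep = 12,
                        maxAnchors = 13, refinePasses = 2)
    expect_lte(median(compareAngleSets(est, truth)), 10)
})

test_that("rotationally symmetric stacks are rejected as degenerate", {
    n <- 25
    g <- expand.grid(x = 1:n, y = 1:n)
    r <- sqrt((g$x - 13)^2 + (g$y - 13)^2)
    ball <- matrix(exp(-r^2 / 30), n, n)
    st <- ClusterStack(list(ball, ball, ball), pixelSize = 10)
    expect_error(assignAngles(st), "degenerate")
})

test_that("back-projection obeys its elementary identities", {
    n <- 21
    g <- expand.grid(x = 1:n, y = 1:n)
    img <- matrix(exp(-((g$x - 8)^2 + (g$y - 14)^2) / 20), n, n)
    st <- ClusterStack(list(img), pixelSize = 10)
    ang <- EulerAngleSet(rbind(c(0, 0, 0)))
    vol <- suppressWarnings(backprojectVolume(st, ang, rampFilter = FALSE,
                                              orientationWeights = FALSE,
                                              normalize = FALSE))
    v <- voxelData(vol)
    # constant along the beam (z) axis
    spread <- apply(v, c(1, 2), function(col) diff(range(col)))
    expect_lt(max(spread), 1e-9 * max(abs(v)))
    # linearity: doubling the input doubles the un-normalized volume
    st2 <- ClusterStack(list(2 * img), pixelSize = 10)
    vol2 <- suppressWarnings(backprojectVolume(st2, ang, rampFilter = FALSE,
                                               orientationWeights = FALSE,
                                               normalize = FALSE))
    expect_equal(voxelData(vol2), 2 * v, tolerance = 1e-12)
})

test_that("shell phantoms reconstruct with an interior density dip", {
    shl <- phantomVolume("shell", n = 36, voxelSize = 9)
    truth <- randomEulerAngles(16, seed = 77)
    stack <- projectPhantom(shl, truth)
    rec <- backprojectVolume(stack, truth)
    v <- voxelData(rec)
    nn <- dim(v)[1]; c0 <- (nn + 1) / 2
    ax <- (seq_len(nn) - c0) * 9
    g <- expand.grid(x = ax, y = ax, z = ax)
    r <- sqrt(g$x^2 + g$y^2 + g$z^2)
    prof <- tapply(as.vector(v), floor(r / 18) + 1, mean)
    core <- prof[1]                       # r < 18 nm
    peak <- max(prof[1:9])
    expect_lt(core, 0.75 * peak)
})

test_that("re-projection validates the reconstruction and flags bad angles", {
    vol <- phantomVolume("asymmetric", n = 36, voxelSize = 9)
    truth <- randomEulerAngles(14, seed = 79)
    stack <- projectPhantom(vol, truth)
    rec <- backprojectVolume(stack, truth)
    val <- reprojectAndValidate(rec, truth, stack)
    expect_gt(val$median, 0.9)
    shuffled <- EulerAngleSet(eulerAngles(truth)[c(8:14, 1:7), ],
                              mirrorAmbiguous = TRUE)
    valBad <- reprojectAndValidate(rec, shuffled, stack)
    expect_lt(valBad$median, val$median)
})

test_that("reconstructions differing by a global rotation match radially", {
    shl <- phantomVolume("shell", n = 30, voxelSize = 10)
    truth <- randomEulerAngles(12, seed = 81)
    stack <- projectPhantom(shl, truth)
    rot <- eulerAngles(truth)
    rot[, 3] <- (rot[, 3] + 55) %% 360     # global rotation of the object
    recA <- backprojectVolume(stack, truth)
    recB <- backprojectVolume(stack, EulerAngleSet(rot))
    radial <- function(rec) {
        v <- voxelData(rec); nn <- dim(v)[1]; c0 <- (nn + 1) / 2
        ax <- (seq_len(nn) - c0) * 10
        g <- expand.grid(x = ax, y = ax, z = ax)
        tapply(as.vector(v), floor(sqrt(g$x^2 + g$y^2 + g$z^2) / 20) + 1, mean)
    }
    pa <- radial(recA); pb <- radial(recB)
    expect_equal(pa[1:7], pb[1:7], tolerance = 0.08)
})
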