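test_that("manual picking extracts boxes at the requested centers", {
    sim <- shellField(nClusters = 3, nMol = 300, seed = 51)
    st <- pickClusters(sim$table, centers = sim$centers[, 1:2], box = 500,
                       pixelSize = 20)
    expect_equal(length(st), 3)
    expect_equal(stackInfo(st)$cx, sim$centers[, 1])
    d <- boxSizePx(st)
    expect_identical(d %% 2L, 1L)           # odd box, centre pixel defined
    # empty image gives an empty stack
    empty <- PixelImage(matrix(0, 50, 50), 20)
    expect_equal(length(suppressWarnings(
        pickClusters(empty, centers = matrix(c(2000, 2000), 1)))), 0)
})

test_that("automatic detection finds all clusters near their true centers", {
    sim <- shellField(nClusters = 5, nMol = 500, seed = 53, fieldNm = 3000)
    st <- pickClusters(sim$table, box = 500, pixelSize = 20,
                       percentile = 0.99, minSeparation = 400)
    expect_equal(length(st), 5)
    found <- as.matrix(stackInfo(st)[, c("cx", "cy")])
    err <- vapply(seq_len(5), function(i)
        min(sqrt(rowSums(sweep(found, 2, sim$centers[i, 1:2])^2))), numeric(1))
    expect_true(all(err < 50))
})

test_that("boxes crossing the image border are skipped with a warning", {
    img <- PixelImage(matrix(runif(2500), 50, 50), 20)
    expect_warning(st <- pickClusters(img, centers = rbind(c(30, 500),
                                                           c(500, 500)),
                                      box = 400), "skipped")
    expect_equal(length(st), 1)
})

test_that("normalization divides by the pixel standard deviation only", {
    withr::with_seed(3, {
        imgs <- list(matrix(runif(121), 11, 11) * 2,
                     matrix(runif(121), 11, 11))
    })
    st <- ClusterStack(imgs, pixelSize = 20)
    nm <- normalizeImages(st)
    expect_equal(sd(stackImages(nm)[[1]]), 1, tolerance = 1e-12)
    # the mean is NOT removed
    expect_gt(mean(stackImages(nm)[[1]]), 0.5)
    # idempotent
    again <- normalizeImages(nm)
    expect_equal(stackImages(again)[[1]], stackImages(nm)[[1]],
                 tolerance = 1e-12)
    flat <- ClusterStack(list(matrix(1, 5, 5)), pixelSize = 20)
    expect_error(normalizeImages(flat), "flat")
})

test_that("known shifts are recovered by alignment to the rotational mean", {
    base <- shellField(nClusters = 1, nMol = 2000, seed = 55, fieldNm = 1000)
    img <- pixelData(renderHistogram(base$table, 20,
        bounds = sim_bounds <- c(sim0 <- base$centers[1, 1] - 260, sim0 + 520,
                                 sim1 <- base$centers[1, 2] - 260, sim1 + 520)))
    withr::with_seed(56, {
        shifts <- matrix(runif(2 * 12, -5, 5), ncol = 2)
    })
    imgs <- lapply(seq_len(12), function(i)
        CentroSMLM:::shiftImage(img, shifts[i, 1], shifts[i, 2]))
    st <- normalizeImages(ClusterStack(imgs, pixelSize = 20))
    al <- alignToRotationalMean(st, nIterations = 4, rotStep = 0)
    rec <- as.matrix(stackInfo(al)[, c("dx", "dy")])
    resid <- rec + shifts                     # aligning undoes the shift
    resid <- sweep(resid, 2, colMeans(resid)) # up to a common offset
    expect_lt(max(abs(resid)), 0.5)
    # contrast of the aligned sum is at least that of the unaligned sum
    contrast <- function(stack) sd(Reduce(`+`, stackImages(stack)))
    expect_gte(contrast(al), contrast(st) - 1e-9)
})

test_that("rotational averaging is a fixed point on symmetric images", {
    withr::with_seed(6, m <- matrix(runif(441), 21, 21))
    sym <- rotationalAverageImage(m)
    again <- rotationalAverageImage(sym)
    expect_lt(max(abs(again - sym)), 1e-6 * max(abs(sym)))
    # constant image has a flat profile equal to the constant
    prof <- radialProfileImage(matrix(3, 21, 21), pixelSize = 20)
    expect_true(all(abs(profileDensity(prof) - 3) < 1e-12))
})

test_that("per-cell statistics follow the sample-sd convention", {
    withr::with_seed(7, img <- matrix(runif(225), 15, 15))
    st <- ClusterStack(list(img, img, img, img), pixelSize = 20,
                       info = data.frame(cell = c(1L, 1L, 2L, 2L),
                                         cluster = 1:4, dx = 0, dy = 0,
                                         rotation = 0, normalized = TRUE))
    prof <- perCellProfileStats(st)
    expect_true(all(profileSd(prof) < 1e-12))   # identical cells
    img2 <- img * 2
    st2 <- ClusterStack(list(img, img2), pixelSize = 20,
                        info = data.frame(cell = 1:2, cluster = 1:2, dx = 0,
                                          dy = 0, rotation = 0,
                                          normalized = TRUE))
    prof2 <- perCellProfileStats(st2)
    p <- profilePerCell(prof2)[1, ]; q <- profilePerCell(prof2)[2, ]
    expect_equal(profileSd(prof2), abs(p - q) / sqrt(2), tolerance = 1e-12)
    expect_equal(profileMean(prof2), (p + q) / 2, tolerance = 1e-12)
})

test_that("half-radius matches the analytic disk, point and shell cases", {
    mkProfile <- function(values, d) new("RadialProfile", binWidth = d,
        binCenters = (seq_along(values) - 0.5) * d, raw = values,
        density = values, normalized = values / sum(values),
        perCell = matrix(numeric(0), 0, length(values)),
        mean = numeric(0), sd = numeric(0))
    # uniform disk of radius 100: constant density over five 20 nm bins
    disk <- mkProfile(c(rep(1, 5), rep(0, 5)), 20)
    expect_equal(halfRadius(disk), 50, tolerance = 1e-12)
    # all mass at the center
    point <- mkProfile(c(1, rep(0, 99)), 1)
    expect_lt(halfRadius(point), 1)
    # thin shell at 80 nm
    shellP <- mkProfile(replace(rep(0, 100), 81, 1), 1)
    expect_equal(halfRadius(shellP), 80.5, tolerance = 0.51)
    expect_error(halfRadius(mkProfile(rep(0, 5), 20)), "zero")
})

test_that("the center of mass follows the stated formula", {
    tab <- LocalizationTable(x = c(0, 2, 1), y = c(0, 0, 3))
    cm <- CentroSMLM:::clusterCenterOfMass(tab, c(0.5, 0.5),
                                           searchRadius = 250)
    expect_equal(cm$M, c(1, 1))
    expect_equal(cm$N, 3L)
})

test_that("ring areas telescope to the disk area", {
    d <- 20
    expect_equal(ringArea(1, d), pi * 400)
    expect_equal(sum(ringArea(1:10, d)), pi * 200^2)
})

test_that("area correction flattens a uniform disk profile", {
    withr::with_seed(61, {
        n <- 1e5
        r <- 200 * sqrt(runif(n))
        th <- runif(n, 0, 2 * pi)
        tab <- LocalizationTable(x = r * cos(th), y = r * sin(th))
    })
    prof <- comRadialProfile(tab, centers = rbind(c(0, 0)),
                             searchRadius = 250, rmax = 200, binWidth = 20)
    v <- profileMean(prof)
    expect_lt(max(v) / min(v), 1.15)
    expect_equal(sum(profileNormalized(prof)), 1, tolerance = 1e-9)
})

test_that("profiles are invariant to rigid motion of the table", {
    sim <- shellField(nClusters = 2, nMol = 400, seed = 63, background = 0)
    p0 <- comRadialProfile(sim$table, sim$centers[, 1:2])
    d <- locData(sim$table)
    th <- 70 * pi / 180
    rot <- function(x, y) cbind(cos(th) * x - sin(th) * y + 777,
                                sin(th) * x + cos(th) * y - 333)
    xy <- rot(d$x, d$y)
    tab2 <- LocalizationTable(x = xy[, 1], y = xy[, 2], frame = d$frame)
    p1 <- comRadialProfile(tab2, rot(sim$centers[, 1], sim$centers[, 2]))
    expect_equal(profileMean(p1), profileMean(p0), tolerance = 1e-9)
})

test_that("two-channel rosettes place the core channel at smaller radii", {
    centers <- rbind(c(600, 600, 300), c(1500, 600, 300),
                     c(600, 1500, 300), c(1500, 1500, 300))
    models <- c(
        lapply(seq_len(4), function(i)
            ClusterModel("shell", 280, 100, nMolecules = 500L,
                         center = centers[i, ], channel = 1L)),
        lapply(seq_len(4), function(i)
            ClusterModel("filled", 100, nMolecules = 200L,
                         center = centers[i, ], channel = 2L)))
    acq <- AcquisitionModel(nFrames = 5000L, meanOnFrames = 3,
                            locPrecision = 10, backgroundDensity = 1e-3,
                            fieldSize = c(2100, 2100, 600), seed = 65L)
    sim <- simulateField(models, acq, dims = 2)
    tab <- mergeConsecutive(sim$table)
    profA <- comRadialProfile(tab, centers[, 1:2], centerChannel = 1L)
    profB <- comRadialProfile(tab, centers[, 1:2], centerChannel = 1L,
                              profileChannel = 2L)
    peakA <- which.max(profileMean(profA))
    peakB <- which.max(profileMean(profB))
    expect_lt(peakB, peakA)
    expect_lte(peakB, 2)
    expect_gte(peakA, 3)
})
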