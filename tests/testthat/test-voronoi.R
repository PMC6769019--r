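test_that("the center cell of a square-plus-center is half the square", {
    s <- 2
    tab <- LocalizationTable(x = c(0, s, 0, s, s / 2), y = c(0, 0, s, s, s / 2))
    vd <- voronoiDensities(tab, dims = 2)
    st <- densityStats(vd)
    expect_equal(st$measure[5], s^2 / 2, tolerance = 1e-9)
    expect_true(st$finite[5])
    # all four corner cells touch the window: flagged unbounded
    expect_false(any(st$finite[1:4]))
    # center is Delaunay-adjacent to every corner
    e <- delaunayEdges(vd)
    expect_true(all(1:4 %in% c(e[e[, 1] == 5, 2], e[e[, 2] == 5, 1])))
})

test_that("mean Voronoi density matches the point density of a uniform field", {
    n <- 3000
    withr::with_seed(21, {
        tab <- LocalizationTable(x = runif(n, 0, 2000), y = runif(n, 0, 2000))
    })
    vd <- voronoiDensities(tab, dims = 2)
    st <- densityStats(vd)
    fin <- st$finite
    expect_equal(mean(1 / st$measure[fin]), n / (2000 * 2000),
                 tolerance = 0.05)
    expect_error(voronoiDensities(LocalizationTable(x = 1:5, y = 1:5)),
                 "collinear")
})

test_that("density maps peak inside clusters and scale with density", {
    sim <- shellField(nClusters = 1, nMol = 400, seed = 25, fieldNm = 1200,
                      background = 1e-3)
    vd <- voronoiDensities(sim$table, dims = 2)
    map <- renderDensityMap(vd, sim$table, pixelSize = 20)
    px <- pixelData(map)
    pk <- arrayInd(which.max(px), dim(px))
    peakXY <- imageOrigin(map) + (pk - 0.5) * 20
    expect_lt(sqrt(sum((peakXY - sim$centers[1, 1:2])^2)), 140 + 20)
    # doubling the localization density doubles the mean map value
    mkUniform <- function(n, seed) withr::with_seed(seed,
        LocalizationTable(x = runif(n, 0, 2000), y = runif(n, 0, 2000)))
    u1 <- mkUniform(2000, 26); u2 <- mkUniform(4000, 27)
    b <- c(200, 1800, 200, 1800)
    m1 <- mean(pixelData(renderDensityMap(voronoiDensities(u1, dims = 2), u1,
                                          40, bounds = b, maxDistance = 1e9)))
    m2 <- mean(pixelData(renderDensityMap(voronoiDensities(u2, dims = 2), u2,
                                          40, bounds = b, maxDistance = 1e9)))
    expect_equal(m2 / m1, 2, tolerance = 0.1)
})

test_that("a pure background field renders a near-uniform map", {
    withr::with_seed(31, {
        tab <- LocalizationTable(x = runif(4000, 0, 4000),
                                 y = runif(4000, 0, 4000))
    })
    vd <- voronoiDensities(tab, dims = 2)
    map <- renderDensityMap(vd, tab, pixelSize = 400, maxDistance = 1e9,
                            bounds = c(0, 4000, 0, 4000))
    px <- pixelData(map)
    expect_lt(sd(px) / mean(px), 0.5)
})

test_that("five shell clusters are segmented with high membership accuracy", {
    sim <- shellField(nClusters = 5, nMol = 500, seed = 33, fieldNm = 3000,
                      background = 2e-3)
    vd <- voronoiDensities(sim$table, dims = 2)
    seg <- segmentClusters(vd, sim$table, alpha = 0.05, nSim = 5,
                           minSize = 50, seed = 8)
    expect_equal(nrow(clusterTable(seg)), 5)
    truthIds <- moleculeIds(sim$truth)
    molPerCluster <- 500L
    trueCluster <- (truthIds - 1L) %/% molPerCluster + 1L   # NA = background
    lab <- clusterLabels(seg)
    ok <- 0; tot <- 0
    for (k in seq_len(5)) {
        members <- which(lab == k)
        trueLab <- trueCluster[members]
        tot <- tot + length(members)
        ok <- ok + max(table(trueLab, useNA = "no"))
    }
    expect_gte(ok / tot, 0.9)
    # recovered sizes compatible with the configured 250-300 nm geometry
    expect_true(all(clusterTable(seg)$eqDiameter > 200 &
                    clusterTable(seg)$eqDiameter < 400))
})

test_that("threshold extremes give the trivial segmentations", {
    sim <- shellField(nClusters = 2, nMol = 200, seed = 35, background = 0)
    vd <- voronoiDensities(sim$table, dims = 2)
    segAll <- segmentClusters(vd, sim$table, threshold = 0, minSize = 1,
                              maxEdge = Inf)
    expect_equal(nrow(clusterTable(segAll)), 1)
    expect_true(all(clusterLabels(segAll) == 1))
    top <- max(densityStats(vd)$densityAvg, na.rm = TRUE)
    segNone <- segmentClusters(vd, sim$table, threshold = top * 2)
    expect_equal(nrow(clusterTable(segNone)), 0)
    expect_true(all(clusterLabels(segNone) == 0))
})

test_that("cluster count is non-increasing in the threshold", {
    sim <- shellField(nClusters = 4, nMol = 300, seed = 37, background = 2e-3)
    vd <- voronoiDensities(sim$table, dims = 2)
    qs <- stats::quantile(densityStats(vd)$densityAvg,
                          c(0.5, 0.8, 0.9, 0.97, 0.995), na.rm = TRUE)
    counts <- vapply(qs, function(t)
        nrow(clusterTable(segmentClusters(vd, sim$table, threshold = t,
                                          minSize = 25))), numeric(1))
    expect_true(all(diff(counts) <= 0))
    expect_gt(counts[1], 0)
})

test_that("segmentation labels are invariant to rigid motions", {
    sim <- shellField(nClusters = 3, nMol = 300, seed = 39, background = 1e-3)
    vd <- voronoiDensities(sim$table, dims = 2)
    seg <- segmentClusters(vd, sim$table, threshold = 1e-4, minSize = 25)
    d <- locData(sim$table)
    th <- 30 * pi / 180
    x2 <- cos(th) * d$x - sin(th) * d$y + 5000
    y2 <- sin(th) * d$x + cos(th) * d$y - 2000
    tab2 <- LocalizationTable(x = x2, y = y2, frame = d$frame)
    vd2 <- voronoiDensities(tab2, dims = 2)
    seg2 <- segmentClusters(vd2, tab2, threshold = 1e-4, minSize = 25)
    # identical up to numerically marginal border cells
    expect_gt(mean(clusterLabels(seg2) == clusterLabels(seg)), 0.995)
})

test_that("the discrete 3D tessellation recovers volumes and clusters", {
    # uniform 3D cube: mean density close to n / volume
    n <- 1500
    withr::with_seed(41, {
        tab <- LocalizationTable(x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                                 z = runif(n, 0, 1000))
    })
    vd <- voronoiDensities(tab, dims = 3, voxelSize = 12)
    st <- densityStats(vd)
    expect_equal(mean(st$density[st$finite], na.rm = TRUE) /
                 (n / 1000^3), 1, tolerance = 0.25)
    # two 3D shells plus background segment into two clusters
    sim <- shellField(nClusters = 2, nMol = 600, seed = 43, dims = 3,
                      fieldNm = 1600, background = 1e-3)
    vd3 <- voronoiDensities(sim$table, dims = 3, voxelSize = 10)
    seg <- segmentClusters(vd3, sim$table, alpha = 0.02, nSim = 2,
                           minSize = 80, seed = 2)
    expect_equal(nrow(clusterTable(seg)), 2)
})
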