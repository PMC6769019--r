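test_that("noise-free shell localizations lie between the shell radii", {
    m <- ClusterModel("shell", 280, 100, nMolecules = 300L,
                      center = c(500, 500, 300))
    acq <- AcquisitionModel(nFrames = 200L, meanOnFrames = 1, locPrecision = 0,
                            backgroundDensity = 0,
                            fieldSize = c(1000, 1000, 600), seed = 2L)
    sim <- simulateField(list(m), acq, dims = 3)
    r <- sqrt(rowSums(sweep(locCoords(sim$table), 2, c(500, 500, 300))^2))
    expect_true(all(r >= 50 & r <= 140))
    expect_true(all(!is.na(moleculeIds(sim$truth))))
})

test_that("identical seeds give bit-identical tables", {
    m <- ClusterModel("filled", 280, nMolecules = 100L, center = c(400, 400, 300))
    acq <- AcquisitionModel(nFrames = 500L, backgroundDensity = 0.01,
                            fieldSize = c(800, 800, 600), seed = 99L)
    a <- simulateField(list(m), acq, dims = 2)
    b <- simulateField(list(m), acq, dims = 2)
    expect_identical(locData(a$table), locData(b$table))
    acq2 <- AcquisitionModel(nFrames = 500L, backgroundDensity = 0.01,
                             fieldSize = c(800, 800, 600), seed = 100L)
    c <- simulateField(list(m), acq2, dims = 2)
    expect_false(identical(locData(a$table), locData(c$table)))
})

test_that("shell radial histogram peaks in the shell and is empty at center", {
    m <- ClusterModel("shell", 280, 100, nMolecules = 500L,
                      center = c(0, 0, 0))
    acq <- AcquisitionModel(nFrames = 2000L, meanOnFrames = 1,
                            locPrecision = 10, backgroundDensity = 0,
                            fieldSize = c(800, 800, 800), seed = 5L)
    sim <- simulateField(list(m), acq, dims = 3)
    r <- sqrt(rowSums(locCoords(sim$table)^2))
    h <- hist(r, breaks = seq(0, 250, 10), plot = FALSE)
    mode <- h$mids[which.max(h$counts)]
    expect_gte(mode, 50)
    expect_lte(mode, 140)
    dens <- h$counts / (h$mids^2)          # 3D shell: counts scale with r^2
    expect_lt(mean(dens[h$mids < 30]), 0.2 * max(dens, na.rm = TRUE))
})

test_that("localization counts match blinking statistics", {
    nMol <- 2000L; meanOn <- 3
    m <- ClusterModel("filled", 280, nMolecules = nMol, center = c(0, 0, 0))
    acq <- AcquisitionModel(nFrames = 20000L, meanOnFrames = meanOn,
                            locPrecision = 10, backgroundDensity = 0,
                            fieldSize = c(1000, 1000, 600), seed = 31L)
    sim <- simulateField(list(m), acq, dims = 2)
    expected <- nMol * meanOn
    se <- sqrt(nMol * meanOn * (meanOn - 1) + nMol * meanOn) # geometric runs
    expect_lt(abs(length(sim$table) - expected), 3 * se + 3 * meanOn)
})

test_that("a shell with zero cavity reduces to a uniform ball", {
    m <- new("ClusterModel", kind = "shell", outerDiameter = 200,
             innerDiameter = 0, nMolecules = 20000L, subclusterCount = 0L,
             center = c(0, 0, 0), channel = 1L)
    acq <- AcquisitionModel(nFrames = 30000L, meanOnFrames = 1,
                            locPrecision = 0, backgroundDensity = 0,
                            fieldSize = c(600, 600, 600), seed = 13L)
    sim <- simulateField(list(m), acq, dims = 3)
    r <- sqrt(rowSums(locCoords(sim$table)^2))
    h <- hist(r, breaks = seq(0, 100, 10), plot = FALSE)
    dens <- h$counts / diff(h$breaks^3)    # d(count)/d(r^3) flat for uniform
    expect_lt(max(dens) / min(dens), 1.35)
})

test_that("bead simulation honours the chromatic model and pairing", {
    ident <- ChromaticModel()
    b <- simulateBeads(20, chromatic = ident, sigma = 0, seed = 4)
    d <- locData(b)
    a1 <- d[d$channel == 1, ]; a2 <- d[d$channel == 2, ]
    expect_equal(a2$x[match(a1$id, a2$id)], a1$x)
    cm <- ChromaticModel(rbind(c(50, 0), matrix(0, 5, 2)))
    b2 <- simulateBeads(50, chromatic = cm, sigma = 0, seed = 4)
    d2 <- locData(b2)
    p1 <- d2[d2$channel == 1, ]; p2 <- d2[d2$channel == 2, ]
    p2 <- p2[match(p1$id, p2$id), ]
    expect_equal(p2$x - p1$x, rep(50, 50))
    expect_equal(p2$y - p1$y, rep(0, 50))
    expect_error(simulateBeads(5, chromatic = ident, sigma = 0, seed = 1),
                 "underdetermined")
})

test_that("dims = 2 rejects axial drift and drops z", {
    m <- ClusterModel("filled", nMolecules = 10L, center = c(100, 100, 100))
    drift3 <- DriftTrajectory(matrix(0, 100, 3))
    acq <- AcquisitionModel(nFrames = 100L, drift = drift3,
                            fieldSize = c(300, 300, 300), seed = 1L)
    expect_error(simulateField(list(m), acq, dims = 2), "axial")
    acq2 <- AcquisitionModel(nFrames = 100L, fieldSize = c(300, 300, 300),
                             seed = 1L)
    expect_identical(locDims(simulateField(list(m), acq2, dims = 2)$table), 2L)
})

test_that("phantom projections respect symmetry and definitions", {
    shl <- phantomVolume("shell", n = 32, voxelSize = 12)
    ang <- EulerAngleSet(rbind(c(0, 0, 0), c(40, 60, 10), c(200, 120, 80)))
    st <- projectPhantom(shl, ang)
    expect_lt(max(abs(stackImages(st)[[1]] - stackImages(st)[[2]])),
              0.02 * max(stackImages(st)[[1]]))
    direct <- apply(voxelData(shl), c(1, 2), sum)
    expect_equal(stackImages(st)[[1]], direct, tolerance = 1e-10)
    bad <- Volume3D(array(0, c(4, 4, 5)), 8)
    expect_error(projectPhantom(bad, ang), "cubic")
})
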